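// Minimal 16-bit grayscale PNG writer (the installed png package reads
// 16-bit PNGs but only writes 8-bit). Non-interlaced, filter type 0,
// zlib-compressed via the system zlib.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
using namespace Rcpp;

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static void write_chunk(FILE* f, const char type[4],
                        const std::vector<unsigned char>& data) {
  unsigned char len[4] = {
    (unsigned char)((data.size() >> 24) & 0xff),
    (unsigned char)((data.size() >> 16) & 0xff),
    (unsigned char)((data.size() >> 8) & 0xff),
    (unsigned char)(data.size() & 0xff)};
  fwrite(len, 1, 4, f);
  fwrite(type, 1, 4, f);
  if (!data.empty()) fwrite(data.data(), 1, data.size(), f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (!data.empty()) crc = crc32(crc, data.data(), data.size());
  unsigned char cb[4] = {
    (unsigned char)((crc >> 24) & 0xff), (unsigned char)((crc >> 16) & 0xff),
    (unsigned char)((crc >> 8) & 0xff), (unsigned char)(crc & 0xff)};
  fwrite(cb, 1, 4, f);
}

// [[Rcpp::export]]
void cpp_write_png16(const IntegerMatrix& m, std::string path) {
  const int H = m.nrow(), W = m.ncol();
  std::vector<unsigned char> raw((size_t)H * (1 + 2 * W));
  size_t p = 0;
  for (int i = 0; i < H; ++i) {
    raw[p++] = 0;  // filter: none
    for (int j = 0; j < W; ++j) {
      const int v = m(i, j);
      raw[p++] = (v >> 8) & 0xff;
      raw[p++] = v & 0xff;
    }
  }
  uLongf clen = compressBound(raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), raw.size(), 9) != Z_OK)
    stop("zlib compression failed");
  comp.resize(clen);

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W);
  put_u32(ihdr, (uint32_t)H);
  ihdr.push_back(16);  // bit depth
  ihdr.push_back(0);   // grayscale
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  write_chunk(f, "IHDR", ihdr);
  write_chunk(f, "IDAT", comp);
  write_chunk(f, "IEND", std::vector<unsigned char>());
  std::fclose(f);
}
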