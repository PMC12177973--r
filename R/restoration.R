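#' Restore (inpaint) masked marker regions
#'
#' Fills the detected fiducial-marker regions with content synthesised
#' from the surrounding image while leaving every unmasked pixel
#' bit-identical to the input (enforced by a final compositing step).
#' Two classical backends are registered: `"diffusion"` (default) fills
#' each masked component with the harmonic interpolant of its boundary
#' values (onion-peel initialisation + successive over-relaxation), and
#' `"nearest"` keeps the onion-peel fill only. Both are deterministic.
#' Additional backends can be registered with [register_inpaint_backend()].
#'
#' The mask is dilated by `dilate` px before filling so that the
#' anti-aliased rim of a marker does not leak into the restored content.
#'
#' @param img An [rgb_image()] (the original slide `I`).
#' @param mask A [binary_mask()] of the regions to fill (the binarized
#'   marker prediction), same size as `img`.
#' @param backend Backend id.
#' @param dilate Mask dilation radius in px applied before filling.
#' @param max_iter,tol SOR iteration cap and convergence tolerance
#'   (diffusion backend).
#' @return An [rgb_image()] with masked regions filled.
#' @examples
#' img <- rgb_image(array(128, c(32, 32, 3)))
#' m <- matrix(0L, 32, 32); m[15:18, 15:18] <- 1L
#' out <- inpaint(img, binary_mask(m))
#' @export
inpaint <- function(img, mask, backend = "diffusion", dilate = 2L,
                    max_iter = 2000L, tol = 0.02) {
  stopifnot(inherits(img, "rgb_image"))
  m <- as.matrix(mask)
  if (!identical(dim(m), dim(img)[1:2]))
    stop("mask dimensions must equal image dimensions", call. = FALSE)
  if (all(m == 1L))
    stop("mask covers the entire image; nothing to condition on",
         call. = FALSE)
  fn <- .inpaint_backends[[backend]]
  if (is.null(fn))
    stop("unknown inpainting backend '", backend, "'; registered: ",
         paste(names(.inpaint_backends), collapse = ", "), call. = FALSE)
  if (!any(m == 1L)) return(img)
  work <- if (dilate > 0) dilate_mask(m, dilate) else m
  if (all(work == 1L))
    stop("dilated mask covers the entire image", call. = FALSE)
  out <- fn(unclass(img), work, max_iter = max_iter, tol = tol)
  # strict no-touch guarantee outside the (dilated) mask
  keep <- work == 0L
  for (ch in 1:3) {
    o <- out[, , ch]; i <- unclass(img)[, , ch]
    o[keep] <- i[keep]
    out[, , ch] <- o
  }
  rgb_image(out)
}

dilate_mask <- function(m, r) {
  out <- matrix(as.integer(m == 1L), nrow(m), ncol(m))
  # exact disc-radius dilation via shifting, cheap for small r
  h <- nrow(m); w <- ncol(m)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr * dr + dc * dc > r * r) next
    rs <- max(1, 1 + dr):min(h, h + dr)
    rt <- max(1, 1 - dr):min(h, h - dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    ct <- max(1, 1 - dc):min(w, w - dc)
    out[rt, ct] <- pmax(out[rt, ct], m[rs, cs])
  }
  out
}

.inpaint_backends <- new.env(parent = emptyenv())

#' Register an inpainting backend
#'
#' A backend is `function(img_array, mask_matrix, max_iter, tol)` that
#' returns an `H x W x 3` array; only masked pixels in its output are
#' used. This is the plug-in point where a learned model could replace
#' the classical default.
#'
#' @param name Backend id.
#' @param fn Backend function.
#' @return `name`, invisibly.
#' @export
register_inpaint_backend <- function(name, fn) {
  assign(name, fn, envir = .inpaint_backends)
  invisible(name)
}

register_inpaint_backend("diffusion", function(img, mask, max_iter, tol) {
  cpp_inpaint(img, mask, refine = 1L, max_iter = as.integer(max_iter),
              tol = tol, omega = 1.9)
})

register_inpaint_backend("nearest", function(img, mask, max_iter, tol) {
  cpp_inpaint(img, mask, refine = 0L, max_iter = 0L, tol = tol, omega = 1)
})

#' Patch-based restoration for large slides
#'
#' Processes each masked component inside a local patch plus halo
#' context, leaving the rest of the slide untouched. Because the
#' classical backends only propagate information across a masked
#' component's own boundary, the result equals whole-image processing
#' whenever the backend's support radius is at most the halo. Components
#' larger than the patch are processed at full resolution with a
#' warning.
#'
#' @inheritParams inpaint
#' @param patch_size Patch side length in px.
#' @param halo Context margin around each component in px.
#' @return An [rgb_image()].
#' @export
inpaint_patched <- function(img, mask, patch_size = 1024L, halo = 64L,
                            backend = "diffusion", dilate = 2L,
                            max_iter = 2000L, tol = 0.02) {
  stopifnot(patch_size > 2L * halo)
  m <- as.matrix(mask)
  if (!any(m == 1L)) return(img)
  work <- if (dilate > 0) dilate_mask(m, dilate) else m
  lab <- cpp_label_components(work, 8L)
  k <- attr(lab, "n_components")
  out <- unclass(img)
  h <- nrow(m); w <- ncol(m)
  for (comp in seq_len(k)) {
    pos <- which(lab == comp, arr.ind = TRUE)
    rr <- range(pos[, 1]); cc <- range(pos[, 2])
    if (diff(rr) + 1L > patch_size || diff(cc) + 1L > patch_size) {
      warning("mask component ", comp, " exceeds the patch size; ",
              "processing at full resolution", call. = FALSE)
      r0 <- 1L; r1 <- h; c0 <- 1L; c1 <- w
    } else {
      r0 <- max(1L, rr[1] - halo); r1 <- min(h, rr[2] + halo)
      c0 <- max(1L, cc[1] - halo); c1 <- min(w, cc[2] + halo)
    }
    sub_img <- out[r0:r1, c0:c1, , drop = FALSE]
    sub_mask <- matrix(as.integer(lab[r0:r1, c0:c1] == comp),
                       r1 - r0 + 1L, c1 - c0 + 1L)
    filled <- cpp_inpaint(sub_img, sub_mask,
                          refine = as.integer(backend == "diffusion"),
                          max_iter = as.integer(max_iter), tol = tol,
                          omega = 1.9)
    sel <- sub_mask == 1L
    for (ch in 1:3) {
      o <- out[r0:r1, c0:c1, ch]
      f <- filled[, , ch]
      o[sel] <- f[sel]
      out[r0:r1, c0:c1, ch] <- o
    }
  }
  rgb_image(out)
}
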