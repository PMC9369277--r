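#' Derive a reproducible child seed from a master seed and a string key
#'
#' Cohort generation derives one seed per specimen (and per field) from a
#' single master seed so that any specimen can be regenerated in isolation.
#' The derivation is a polynomial rolling hash of the key's UTF-8 bytes,
#' folded into the master seed modulo 2^31 - 1, so it is identical across
#' platforms and R sessions.
#'
#' @param seed Integer master seed.
#' @param key Character scalar identifying the child stream (e.g. a specimen
#'   id, or `"field003"`).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(key), length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, prime; 31 * m < 2^53 so the arithmetic is exact
  h <- abs(as.numeric(seed)) %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 2) + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Quantize an intensity plane to the 16-bit grid
#'
#' Synthetic planes are snapped to multiples of 1/65535 before any file is
#' written, so TIFF output round-trips bit-exactly.
#' @noRd
quantize16 <- function(x) round(clamp(x, 0, 1) * 65535) / 65535

# Linear indices of the pixels of an annulus (r_in_px = 0 gives a full disk)
# centred at (row0, col0) within a dim_hw = c(H, W) matrix. Returning indices
# lets callers paint with `plane[idx] <- ...`, which modifies in place and
# avoids a full-plane copy per painted object.
annulus_idx <- function(dim_hw, row0, col0, r_out_px, r_in_px = 0) {
  h <- dim_hw[1]; w <- dim_hw[2]
  rr <- max(1L, floor(row0 - r_out_px)):min(h, ceiling(row0 + r_out_px))
  cc <- max(1L, floor(col0 - r_out_px)):min(w, ceiling(col0 + r_out_px))
  if (!length(rr) || !length(cc)) return(integer(0))
  d2 <- outer((rr - row0)^2, (cc - col0)^2, `+`)
  hit <- which(d2 <= r_out_px^2 & d2 >= r_in_px^2, arr.ind = TRUE)
  (cc[hit[, 2]] - 1L) * h + rr[hit[, 1]]
}

# Logical mask of an ellipse (semi-axes a_px, b_px, rotation theta) within a
# full-field matrix of dimensions dim_hw = c(H, W).
ellipse_mask <- function(dim_hw, row0, col0, a_px, b_px, theta) {
  h <- dim_hw[1]; w <- dim_hw[2]
  m <- matrix(FALSE, h, w)
  r_max <- max(a_px, b_px)
  rr <- max(1L, floor(row0 - r_max)):min(h, ceiling(row0 + r_max))
  cc <- max(1L, floor(col0 - r_max)):min(w, ceiling(col0 + r_max))
  if (!length(rr) || !length(cc)) return(m)
  dy <- rr - row0
  dx <- cc - col0
  u <- outer(dy * sin(theta), dx * cos(theta), `+`)   # rotated coords
  v <- outer(dy * cos(theta), -dx * sin(theta), `+`)
  m[rr, cc] <- (u / a_px)^2 + (v / b_px)^2 <= 1
  m
}

match_arg_ci <- function(arg, choices) {
  i <- pmatch(tolower(arg[1L]), tolower(choices))
  if (is.na(i)) stop(sprintf("'%s' must be one of: %s", deparse(substitute(arg)),
                             paste(choices, collapse = ", ")), call. = FALSE)
  choices[i]
}
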