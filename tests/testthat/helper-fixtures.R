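# Small-field configurations keep unit tests fast; recovery-grade checks in
# test-acceptance.R use full-size fields.

tiny_config <- function(tissue_type = "eutopic_endometrium", pixel_um = 2,
                        field_mm = c(0.45, 0.35), noise = c(0.05, 0.02, 0),
                        ...) {
  specimen_config(tissue_type = tissue_type, pixel_um = pixel_um,
                  field_mm = field_mm, noise = noise, ...)
}

noise_free <- c(background = 0, sigma = 0, bleedthrough = 0)

# A channel_stack whose planes are all zero except the ones supplied.
make_stack <- function(dim_hw = c(40L, 50L), pixel_um = 1, ...) {
  planes <- stats::setNames(
    rep(list(matrix(0, dim_hw[1], dim_hw[2])), length(VQ_CHANNELS)),
    VQ_CHANNELS)
  override <- list(...)
  for (nm in names(override)) planes[[nm]] <- override[[nm]]
  channel_stack(planes, pixel_um = pixel_um)
}

# Paint a filled disk / ring into a matrix (row, col, radii in pixels).
mat_disk <- function(m, r0, c0, r_out, r_in = 0, value = 1) {
  d2 <- outer((seq_len(nrow(m)) - r0)^2, (seq_len(ncol(m)) - c0)^2, `+`)
  m[d2 <= r_out^2 & d2 >= r_in^2] <- value
  m
}

# Minimal specimen-level design table for statistics tests.
flat_design <- function(n_per_group, tissue_types, cycle_phase = "proliferative",
                        bvd = 30, lvd = 8, mature = 0.5) {
  pick <- function(x, tt) if (length(x) > 1L) unname(x[[tt]]) else x
  rows <- list()
  for (tt in tissue_types) {
    # myometrium is sampled from cases and controls alike
    grps <- if (tt == "myometrium") c("adenomyosis", "control") else
      if (tt == "control_endometrium") "control" else "adenomyosis"
    for (grp in grps) {
      for (i in seq_len(n_per_group)) {
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = sprintf("%s_%s_%02d", substr(grp, 1, 4), tt, i),
          patient_id = sprintf("%s_p%02d", substr(grp, 1, 4), i),
          group = grp, tissue_type = tt, cycle_phase = cycle_phase,
          medication = "none_other", planted_bvd = pick(bvd, tt),
          planted_lvd = pick(lvd, tt),
          planted_mature_fraction = pick(mature, tt), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
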