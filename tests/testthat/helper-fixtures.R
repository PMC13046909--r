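# Noiseless ROI table built directly from the linear spectral model:
# le = le_base + a_low * C, he = he_base + (a_low / der) * C.
make_linear_roi_table <- function(concentrations = c(0.5, 1, 2, 5, 10, 15),
                                  le_base = -2, he_base = -7,
                                  a_low = 26.3, der = 2.49,
                                  material = "iodine", kv = "140",
                                  dose_pct = 100, fat_ring = FALSE) {
  data.frame(material = material, kv = kv, dose_pct = dose_pct,
             fat_ring = fat_ring, concentration_mg_ml = concentrations,
             le_hu = le_base + a_low * concentrations,
             he_hu = he_base + a_low / der * concentrations,
             stringsAsFactors = FALSE)
}

# Brute-force per-pixel oracle for circular ROI means (pixel-center rule).
brute_force_roi_mean <- function(img, spacing, center, radius) {
  vals <- c()
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      x <- (j - 1) * spacing
      y <- (i - 1) * spacing
      if ((x - center[1])^2 + (y - center[2])^2 <= radius^2) {
        vals <- c(vals, img[i, j])
      }
    }
  }
  list(mean = mean(vals), n = length(vals))
}

expect_rel_equal <- function(object, expected, tol = 1e-9) {
  expect_true(all(abs(object - expected) <=
                    tol * pmax(abs(expected), 1)),
              label = sprintf("max abs diff %.3g", max(abs(object - expected))))
}
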