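# Small in-code fixtures shared across tests.

# a minimal valid metadata frame
make_metadata <- function(n, cultivar = "Alto", strain = "AR1",
                          status = "E+", bag = "bag1") {
  data.frame(bag_id = rep(bag, n), cultivar = rep(cultivar, n),
             endophyte_strain = rep(strain, n),
             endophyte_status = rep(status, n),
             scan_index = seq_len(n), stringsAsFactors = FALSE)
}

# tiny spectra_set with arbitrary absorbance values
make_set <- function(X, grid = nir_grid(100, 100 - 8 * (ncol(X) - 1), 8),
                     metadata = make_metadata(nrow(X))) {
  spectra_set(X, metadata, grid)
}

# compact acquisition-like grid for fast end-to-end tests: 125 points,
# 9000-4040 cm-1 at 40 cm-1, covering all six default band centers
small_grid <- function() nir_grid(9000, 4040, 40)

# two-cultivar, two-status toy design on the small grid
toy_design <- function(n_bags_per_class = 4, scans_per_bag = 6,
                       cultivars = c("Alto", "Trojan")) {
  rows <- list()
  for (cv in cultivars) {
    for (i in seq_len(n_bags_per_class)) {
      status <- if (i == n_bags_per_class) "E-" else "E+"
      strain <- if (status == "E-") "WE" else "AR1"
      rows[[length(rows) + 1L]] <- data.frame(
        bag_id = sprintf("%s_%02d", cv, i), cultivar = cv,
        endophyte_strain = strain, endophyte_status = status,
        stringsAsFactors = FALSE)
    }
  }
  sim_design(do.call(rbind, rows), scans_per_bag = scans_per_bag,
             grid = small_grid())
}

# well-separated two-class matrix for classifier tests
make_separable <- function(n_per_class = 20, p = 10, gap = 6, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  y <- rep(c("A", "B"), each = n_per_class)
  X[y == "A", 1] <- X[y == "A", 1] + gap
  list(X = X, y = y)
}
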