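# programmatic fixtures shared across test files

make_bar <- function(nr = 20, nc = 110, rows = 9:11, cols = 6:105) {
  m <- matrix(0L, nr, nc); m[rows, cols] <- 1L; m
}

make_plus <- function(n = 61, arm = 6:56, core = 30:32) {
  m <- matrix(0L, n, n); m[core, arm] <- 1L; m[arm, core] <- 1L; m
}

make_disk <- function(radius = 20, pad = 5) {
  n <- 2 * (radius + pad) + 1; ctr <- radius + pad + 1
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= radius^2) m[i, j] <- 1L
  m
}

# tiny two-channel image with hand-set pixels for gating tests
tiny_stroma_image <- function() {
  pdpn <- matrix(0, 4, 4); cd31 <- matrix(0, 4, 4)
  pdpn[1, 1] <- 10              # FRC: PDPN+ CD31-
  pdpn[2, 2] <- 10; cd31[2, 2] <- 10   # LEC: PDPN+ CD31+
  cd31[3, 3] <- 10              # BEC
  multiplex_image(list(pdpn, cd31), marker_panel(c("PDPN", "CD31")))
}

# well-separated Gaussian phenotype blobs in marker space
planted_marker_cells <- function(n_per = 100, centers = c(0.1, 0.5, 0.9),
                                 sd = 0.01, seed = 1) {
  withr::with_seed(seed, {
    mk <- c("PD-1", "LAG-3", "TIM-3", "PD-L1", "PD-L2", "GrB")
    rows <- lapply(seq_along(centers), function(i) {
      m <- matrix(pmax(stats::rnorm(n_per * 6, centers[i], sd), 0), n_per, 6,
                  dimnames = list(NULL, mk))
      tibble::as_tibble(m)
    })
    df <- dplyr::bind_rows(rows)
    df$planted <- rep(seq_along(centers), each = n_per)
    df$sample_id <- "s1"; df$core_id <- "c1"
    df$cell_id <- seq_len(nrow(df))
    df
  })
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
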