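#' Published risk-category shift matrix
#'
#' The 5 x 5 cross-tabulation of Agatston risk categories assigned by an
#' expert reference standard (rows) and by fully automated scoring (columns)
#' in a published evaluation on 1749 low-dose non-gated lung-screening chest
#' CT scans. Bundled as example data for the agreement statistics: the suite
#' applied to this matrix yields a proportion of agreement of 79.2%, a
#' linearly weighted kappa of 0.85, 83 subjects shifted by more than one
#' stratum, and 144 (8.2%) false-negative zero scores.
#'
#' @return 5 x 5 integer matrix with [risk_levels] dimnames, reference on
#'   rows.
#' @export
screening_shift_matrix <- function() {
  m <- matrix(c(401, 23,  6,   3,   0,
                94,  88,  11,  0,   0,
                40,  31,  275, 5,   3,
                6,   6,   44,  243, 2,
                4,   1,   14,  70,  379),
              nrow = 5, byrow = TRUE,
              dimnames = list(reference = risk_levels,
                              automated = risk_levels))
  storage.mode(m) <- "integer"
  m
}
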