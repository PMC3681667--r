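#' Simulate a collection of 120-value time profiles with class structure
#'
#' Draws per-protein profiles as a class mean plus independent Gaussian noise
#' scaled by the class sd profile; used to exercise the clustering and
#' enrichment stages against known labels.
#'
#' @param class_defs A list of class definitions, each a list with elements
#'   `mean` (numeric length 120), `sd` (numeric length 120 or scalar) and
#'   `size` (number of member proteins).
#' @param seed Integer seed; fixed seed reproduces the table exactly.
#' @param var_floor Per-entry variance attached to each profile (the
#'   generator's stand-in for LOESS keypoint variances), default 1.
#' @return A list with `profiles`: a tibble (`protein`, `class`, and a
#'   120-column matrix-column `profile`, plus `variance`), and `labels`:
#'   integer class labels.
#' @export
simulate_profile_collection <- function(class_defs, seed = 1L, var_floor = 1) {
  for (cd in class_defs) {
    if (length(cd$mean) != 120L) {
      bp_abort("class mean profile must have exactly 120 entries",
               class = "budprofiler_dimension_error")
    }
    sdv <- rep_len(cd$sd, 120L)
    if (any(sdv < 0)) bp_abort("class sd profile must be non-negative")
  }
  with_seed(seed, {
    rows <- purrr::imap(class_defs, function(cd, k) {
      sdv <- rep_len(cd$sd, 120L)
      prof <- t(vapply(seq_len(cd$size), function(i) {
        cd$mean + rnorm(120L, 0, sdv)
      }, numeric(120L)))
      list(profile = prof, class = rep(k, cd$size))
    })
    profile <- do.call(rbind, purrr::map(rows, "profile"))
    labels <- unlist(purrr::map(rows, "class"))
    n <- length(labels)
    out <- tibble::tibble(
      protein = sprintf("P%04d", seq_len(n)),
      class = labels
    )
    out$profile <- profile
    out$variance <- matrix(var_floor, n, 120L)
    list(profiles = out, labels = labels)
  })
}
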