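#' Default fingerprint dictionary grid
#'
#' Water T1 from 600 to 2000 ms in 25 ms steps, fat fraction 0 to 100 % in
#' 2.5 % steps, B1+ 0.7 to 1.3 in steps of 0.05.
#'
#' @return Named list of grid axes (`t1w_ms`, `ff`, `b1`), each strictly
#'   increasing.
#' @export
default_dictionary_grid <- function() {
  list(t1w_ms = seq(600, 2000, by = 25),
       ff = seq(0, 100, by = 2.5),
       b1 = seq(0.7, 1.3, by = 0.05))
}

#' Build a fingerprint matching dictionary
#'
#' Simulates, with the same forward model as the phantom generator
#' ([mrf_signal()]), one fingerprint per node of the (water T1, FF, B1)
#' grid — a two-compartment sum of a water pool and a fixed-T1 fat pool — and
#' stores it unit-normalized. Regeneration from the same schedule and grid is
#' deterministic.
#'
#' @param schedule A [fingerprint_schedule()].
#' @param grid Named list of axes as in [default_dictionary_grid()]; single
#'   nodes per axis are allowed, empty axes are an error.
#' @param constants Shared constants (fat T1).
#' @return An object of class `fingerprint_dictionary`: `entries` (matrix,
#'   nodes x pulses, unit row norm), `nodes` (tibble `t1w_ms`, `ff`, `b1`),
#'   `schedule`, `grid`.
#' @export
build_dictionary <- function(schedule = fingerprint_schedule(),
                             grid = default_dictionary_grid(),
                             constants = qmri_constants()) {
  if (length(schedule$flip_deg) < 1)
    stop("empty fingerprint schedule", call. = FALSE)
  for (ax in c("t1w_ms", "ff", "b1")) {
    if (length(grid[[ax]]) < 1)
      stop(sprintf("dictionary grid axis '%s' is empty", ax), call. = FALSE)
    if (is.unsorted(grid[[ax]], strictly = TRUE) && length(grid[[ax]]) > 1)
      stop(sprintf("grid axis '%s' must be strictly increasing", ax),
           call. = FALSE)
  }
  np <- length(schedule$flip_deg)
  # node order sorted by (T1w, FF, B1) so a ties.method = "first" argmax
  # breaks exact ties towards the lowest T1w, then the lowest FF
  nodes <- tidyr::expand_grid(t1w_ms = grid$t1w_ms, ff = grid$ff,
                              b1 = grid$b1)
  fat_phase <- exp(2i * pi * ppm_to_hz(constants$fat_ppm) *
                     schedule$te_ms / 1000)
  sw_by_b1 <- lapply(grid$b1, function(b1) mrf_signal(grid$t1w_ms, b1, schedule))
  sf_by_b1 <- lapply(grid$b1, function(b1)
    as.numeric(mrf_signal(constants$fat_t1_ms, b1, schedule)))
  entries <- matrix(complex(real = 0), nrow(nodes), np)
  row <- 0L
  for (it1 in seq_along(grid$t1w_ms)) {
    for (ff in grid$ff) {
      for (ib1 in seq_along(grid$b1)) {
        row <- row + 1L
        entries[row, ] <- (1 - ff / 100) * sw_by_b1[[ib1]][it1, ] +
          (ff / 100) * fat_phase * sf_by_b1[[ib1]]
      }
    }
  }
  nrm <- sqrt(rowSums(Mod(entries)^2))
  nrm[nrm == 0] <- 1
  entries <- entries / nrm
  structure(list(entries = entries, nodes = nodes, schedule = schedule,
                 grid = grid),
            class = "fingerprint_dictionary")
}

#' @export
print.fingerprint_dictionary <- function(x, ...) {
  cat(sprintf("<fingerprint_dictionary> %d entries x %d pulses (T1 %d, FF %d, B1 %d nodes)\n",
              nrow(x$entries), ncol(x$entries), length(x$grid$t1w_ms),
              length(x$grid$ff), length(x$grid$b1)))
  invisible(x)
}

# Exhaustive match of unit-normalized signals (columns of S, complex or real)
# against the dictionary: squared magnitude of the matched-filter inner
# product |e^H s|^2 via four real matrix products. Node rows are sorted by
# (T1w, FF, B1), so ties.method = "first" implements the deterministic
# tie-break towards the lowest T1w, then the lowest FF.
match_index <- function(dict, S) {
  Er <- Re(dict$entries); Ei <- Im(dict$entries)
  Sr <- Re(S); Si <- Im(S)
  A <- Er %*% Sr + Ei %*% Si
  B <- Er %*% Si - Ei %*% Sr
  sc2 <- A^2 + B^2                          # nodes x nsig
  idx <- max.col(t(sc2), ties.method = "first")
  list(idx = idx, score = sqrt(sc2[cbind(idx, seq_len(ncol(sc2)))]))
}

#' Match one signal against a fingerprint dictionary
#'
#' Returns the grid node maximizing the magnitude of the inner product
#' between the unit-normalized signal and the stored fingerprints
#' (exhaustive search). The match is invariant to positive scaling of the
#' signal; ties are broken deterministically towards the lowest water T1,
#' then the lowest FF.
#'
#' @param signal Numeric or complex vector, length equal to the fingerprint
#'   length. A zero signal is masked (all-NA result), not an error.
#' @param dict A [build_dictionary()] result.
#' @return A tibble with `t1w_ms`, `ff`, `b1`, `score`.
#' @export
match_fingerprint <- function(signal, dict) {
  stopifnot(inherits(dict, "fingerprint_dictionary"))
  if (length(signal) != ncol(dict$entries))
    stop("signal length does not match fingerprint length", call. = FALSE)
  nrm <- sqrt(sum(Mod(signal)^2))
  if (nrm == 0)
    return(tibble::tibble(t1w_ms = NA_real_, ff = NA_real_, b1 = NA_real_,
                          score = NA_real_))
  m <- match_index(dict, matrix(signal / nrm, ncol = 1))
  dplyr::bind_cols(dict$nodes[m$idx, c("t1w_ms", "ff", "b1")],
                   tibble::tibble(score = m$score))
}

#' Voxelwise water T1 map by fingerprint matching
#'
#' @param series An [acquisition_series()] of fingerprint time-courses.
#' @param dict A [build_dictionary()] result built with the series' schedule.
#' @param mask Optional logical array of voxels to match (default: voxels
#'   with nonzero signal norm above a small threshold).
#' @param chunk Number of voxels matched per block (memory control).
#' @return A list of class `t1_map_result`: `t1` (a [quantitative_map()] in
#'   ms), `ff` (MRF-internal fat-fraction nuisance estimate, percent), `b1`,
#'   `score` arrays.
#' @export
match_t1_map <- function(series, dict, mask = NULL, chunk = 512L) {
  stopifnot(inherits(series, "acquisition_series"),
            inherits(dict, "fingerprint_dictionary"))
  d <- dim(series$data)[1:3]
  S_all <- matrix(series$data, ncol = dim(series$data)[4])
  if (ncol(S_all) != ncol(dict$entries))
    stop("series and dictionary have different fingerprint lengths",
         call. = FALSE)
  nrm <- sqrt(rowSums(Mod(S_all)^2))
  if (is.null(mask)) mask <- array(nrm > 0.05 * stats::quantile(nrm, 0.99), d)
  vox <- which(mask & array(nrm > 0, d))
  t1 <- array(NA_real_, d); ffm <- array(NA_real_, d)
  b1 <- array(NA_real_, d); sc <- array(NA_real_, d)
  for (start in seq(1, length(vox), by = chunk)) {
    sel <- vox[start:min(start + chunk - 1L, length(vox))]
    S <- t(S_all[sel, , drop = FALSE] / nrm[sel])
    m <- match_index(dict, S)
    t1[sel] <- dict$nodes$t1w_ms[m$idx]
    ffm[sel] <- dict$nodes$ff[m$idx]
    b1[sel] <- dict$nodes$b1[m$idx]
    sc[sel] <- m$score
  }
  structure(list(
    t1 = quantitative_map(t1, parameter = "water_t1", unit = "ms"),
    ff = ffm, b1 = b1, score = sc),
    class = "t1_map_result")
}

#' Fat-fraction exclusion for water T1 maps
#'
#' Voxels whose (Dixon) fat fraction exceeds 60 % are excluded from the water
#' T1 analysis; a voxel at exactly 60 % is retained (strict inequality).
#'
#' @param t1_map A [quantitative_map()] of water T1 (or a `t1_map_result`,
#'   whose `t1` element is used).
#' @param ff_map A co-registered [quantitative_map()] or array of FF (%).
#' @return The T1 [quantitative_map()] with high-FF voxels masked
#'   (`reason = "ff_high"`).
#' @export
apply_t1_exclusion <- function(t1_map, ff_map) {
  if (inherits(t1_map, "t1_map_result")) t1_map <- t1_map$t1
  stopifnot(inherits(t1_map, "quantitative_map"))
  ff <- if (inherits(ff_map, "quantitative_map")) ff_map$values else ff_map
  if (!all(dim(ff) == dim(t1_map$values)))
    stop("FF map and T1 map dimensions differ", call. = FALSE)
  exclude_voxels(t1_map, !is.na(ff) & ff > 60, "ff_high")
}
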