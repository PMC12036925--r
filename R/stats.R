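#' The 18-muscle dictionary
#'
#' Eleven thigh and seven leg muscles with their functional group
#' memberships: quadriceps QUAD = RF, VI, VL, VM; hamstrings HSTR = BF, SM,
#' ST; anterior compartment ANT = TA, TP, ED; fibularis FIB = PER; triceps
#' surae TRIC = GM, GL, SOL. Thigh adductors/gracilis/sartorius belong to no
#' named group.
#'
#' @return A tibble with `code`, `name`, `compartment`, `group`.
#' @export
muscle_dictionary <- function() {
  tibble::tribble(
    ~code, ~name, ~compartment, ~group,
    "AL",  "adductor longus",        "thigh", NA,
    "AM",  "adductor magnus",        "thigh", NA,
    "BF",  "biceps femoris long head", "thigh", "HSTR",
    "GRA", "gracilis",               "thigh", NA,
    "RF",  "rectus femoris",         "thigh", "QUAD",
    "SAR", "sartorius",              "thigh", NA,
    "SM",  "semimembranosus",        "thigh", "HSTR",
    "ST",  "semitendinosus",         "thigh", "HSTR",
    "VI",  "vastus intermedius",     "thigh", "QUAD",
    "VL",  "vastus lateralis",       "thigh", "QUAD",
    "VM",  "vastus medialis",        "thigh", "QUAD",
    "ED",  "extensor digitorum",     "leg",   "ANT",
    "GL",  "gastrocnemius lateralis", "leg",  "TRIC",
    "GM",  "gastrocnemius medialis", "leg",   "TRIC",
    "PER", "peroneus longus",        "leg",   "FIB",
    "SOL", "soleus",                 "leg",   "TRIC",
    "TA",  "tibialis anterior",      "leg",   "ANT",
    "TP",  "tibialis posterior",     "leg",   "ANT"
  )
}

#' Muscle label map
#'
#' An integer-labelled ROI volume together with the table describing each
#' label (code, side, compartment).
#'
#' @param labels Integer 3D array (0 = background).
#' @param muscles Tibble with at least `label`, `code`, `side`,
#'   `compartment`.
#' @return An object of class `muscle_label_map`.
#' @export
muscle_label_map <- function(labels, muscles) {
  muscles <- tibble::as_tibble(muscles)
  stopifnot(length(dim(labels)) == 3,
            all(c("label", "code", "side", "compartment") %in% names(muscles)))
  if (anyDuplicated(muscles$label)) stop("duplicate labels", call. = FALSE)
  structure(list(labels = labels, muscles = muscles),
            class = "muscle_label_map")
}

#' @export
print.muscle_label_map <- function(x, ...) {
  cat(sprintf("<muscle_label_map> %d muscles, %d labelled voxels\n",
              nrow(x$muscles), sum(x$labels > 0)))
  invisible(x)
}

#' Label map of a phantom ground truth
#' @param truth A [phantom_ground_truth()].
#' @return A [muscle_label_map()].
#' @export
as_muscle_label_map <- function(truth) {
  stopifnot(inherits(truth, "phantom_ground_truth"))
  muscle_label_map(truth$labels, truth$truth)
}

#' Per-muscle aggregation of a quantitative map
#'
#' The mean parameter value per muscle is computed over all valid voxels of
#' all segmented slices; the voxel count is recorded and muscles with fewer
#' than 50 valid voxels are excluded (strictly: exactly 50 is retained). A
#' label absent from the map yields a count-0 excluded record rather than an
#' error, so the ledger stays complete.
#'
#' @param map A [quantitative_map()] (voxel-level exclusions already encoded
#'   in its mask).
#' @param labelmap A [muscle_label_map()] co-registered with the map.
#' @param subject,visit,group Identifiers copied into each record.
#' @param min_voxels Minimum valid voxel count for retention.
#' @return A tibble of muscle records: `subject`, `group`, `visit`, `side`,
#'   `muscle`, `compartment`, `parameter`, `mean_value`, `n_voxels`,
#'   `excluded`, `reason`.
#' @export
aggregate_muscle <- function(map, labelmap, subject = "phantom",
                             visit = "BL", group = "patient",
                             min_voxels = 50) {
  stopifnot(inherits(map, "quantitative_map"),
            inherits(labelmap, "muscle_label_map"),
            all(dim(map$values) == dim(labelmap$labels)))
  purrr::pmap_dfr(
    labelmap$muscles[, c("label", "code", "side", "compartment")],
    function(label, code, side, compartment) {
      sel <- labelmap$labels == label & map$mask
      n <- sum(sel)
      mean_val <- if (n > 0) mean(map$values[sel]) else NA_real_
      too_few <- n < min_voxels
      tibble::tibble(
        subject = subject, group = group, visit = visit, side = side,
        muscle = code, compartment = compartment,
        parameter = map$parameter, mean_value = mean_val,
        n_voxels = as.integer(n), excluded = too_few,
        reason = if (too_few) "too_few_voxels" else "none")
    })
}

#' Pixel-weighted average of muscle records
#'
#' `sum(mean_i * n_i) / sum(n_i)` over the retained records in scope. Scopes:
#' `"all"` (every retained record), `"global_thigh"` / `"global_leg"` (by
#' compartment), `"group"` (a named muscle group, via [muscle_dictionary()]).
#'
#' @param records Muscle-record tibble (see [aggregate_muscle()]).
#' @param scope One of `"all"`, `"global_thigh"`, `"global_leg"`, `"group"`.
#' @param group Muscle group code (e.g. `"QUAD"`) when `scope = "group"`.
#' @return The weighted mean (NA with a warning if the scope is empty).
#' @export
weighted_average <- function(records, scope = c("all", "global_thigh",
                                                "global_leg", "group"),
                             group = NULL) {
  scope <- match.arg(scope)
  r <- dplyr::filter(records, !.data$excluded, !is.na(.data$mean_value))
  r <- switch(scope,
    all = r,
    global_thigh = dplyr::filter(r, .data$compartment == "thigh"),
    global_leg = dplyr::filter(r, .data$compartment == "leg"),
    group = {
      if (is.null(group)) stop("group scope needs a group code", call. = FALSE)
      codes <- muscle_dictionary()$code[
        !is.na(muscle_dictionary()$group) & muscle_dictionary()$group == group]
      dplyr::filter(r, .data$muscle %in% codes)
    })
  if (nrow(r) == 0) {
    warning("no retained records in scope; average unavailable", call. = FALSE)
    return(NA_real_)
  }
  sum(r$mean_value * r$n_voxels) / sum(r$n_voxels)
}

#' Merge left and right records into bilateral averages
#'
#' One record per (subject, visit, muscle, parameter), averaging the two
#' sides weighted by voxel count (consistent with the pixel-weighted global
#' averages); counts add. If only one side is present its value is used and
#' the record flagged unilateral.
#'
#' @param records Muscle-record tibble.
#' @return Tibble with `side = "LR"` and an extra `unilateral` flag.
#' @export
bilateral_average <- function(records) {
  records |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$subject, .data$group, .data$visit, .data$muscle,
                    .data$compartment, .data$parameter) |>
    dplyr::summarise(
      mean_value = sum(.data$mean_value * .data$n_voxels) / sum(.data$n_voxels),
      n_voxels = sum(.data$n_voxels),
      unilateral = dplyr::n() < 2,
      .groups = "drop") |>
    dplyr::mutate(side = "LR", excluded = FALSE, reason = "none")
}

#' Cohort bookkeeping totals
#'
#' Number of segmented muscles per modality and group for a longitudinal
#' design: bilateral modalities count every muscle on both sides for every
#' exam; the diffusion modality counts the right-leg muscles only.
#'
#' @param patients_by_visit Named or unnamed integer vector of patient exams
#'   per visit (e.g. `c(BL = 18, y1 = 16, y2 = 16)`).
#' @param controls Number of control exams.
#' @param thigh_muscles,leg_muscles Muscles per compartment (default 11 / 7).
#' @param sides Number of sides for the bilateral modalities.
#' @return A tibble with rows (modality x group) and a `n_muscles` column;
#'   per modality the `total` row equals patients + controls.
#' @export
tally_cohort <- function(patients_by_visit = c(BL = 18, y1 = 16, y2 = 16),
                         controls = 13, thigh_muscles = 11, leg_muscles = 7,
                         sides = 2) {
  p_exams <- sum(patients_by_visit)
  per_exam <- (thigh_muscles + leg_muscles) * sides
  dti_per_exam <- leg_muscles  # right leg only
  tibble::tribble(
    ~modality, ~group, ~n_muscles,
    "bilateral_qmri", "patient", p_exams * per_exam,
    "bilateral_qmri", "control", controls * per_exam,
    "bilateral_qmri", "total", (p_exams + controls) * per_exam,
    "dti", "patient", p_exams * dti_per_exam,
    "dti", "control", controls * dti_per_exam,
    "dti", "total", (p_exams + controls) * dti_per_exam
  )
}

#' Longitudinal change per subject
#'
#' `delta = value(follow-up) - value(baseline)` on complete pairs
#' (completers); subjects missing either visit are dropped with a warning.
#'
#' @param data Tibble with at least `subject`, `visit` and a value column.
#' @param value Name of the value column (string).
#' @param baseline,followup Visit labels.
#' @return A list with `delta` (tibble `subject`, `delta`), `mean`, `sd`,
#'   `n`.
#' @export
delta_over_time <- function(data, value = "mean_value", baseline = "BL",
                            followup = "y2") {
  wide <- data |>
    dplyr::filter(.data$visit %in% c(baseline, followup)) |>
    dplyr::select("subject", "visit", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "visit", values_from = dplyr::all_of(value))
  complete <- !is.na(wide[[baseline]]) & !is.na(wide[[followup]])
  if (any(!complete))
    warning(sprintf("%d unpaired subject(s) dropped", sum(!complete)),
            call. = FALSE)
  wide <- wide[complete, ]
  delta <- wide[[followup]] - wide[[baseline]]
  list(delta = tibble::tibble(subject = wide$subject, delta = delta),
       mean = mean(delta), sd = sd(delta), n = length(delta))
}

#' Standardized response mean
#'
#' Mean change over time divided by the standard deviation of the change
#' (sample SD, n - 1): a responsiveness index for longitudinal biomarkers.
#'
#' @param delta Numeric vector of per-subject changes (or the list returned
#'   by [delta_over_time()]).
#' @return The SRM (NA with a warning when fewer than 2 subjects or zero SD).
#' @export
standardized_response_mean <- function(delta) {
  if (is.list(delta) && !is.null(delta$delta)) delta <- delta$delta$delta
  if (length(delta) < 2) {
    warning("SRM needs at least 2 subjects", call. = FALSE)
    return(NA_real_)
  }
  s <- sd(delta)
  if (s == 0) {
    warning("zero SD of change; SRM unavailable", call. = FALSE)
    return(NA_real_)
  }
  mean(delta) / s
}

#' Spearman rank correlation with a qualitative band
#'
#' Mid-rank ties; the band label follows the conventional cut points:
#' |rho| 0-0.19 very weak, 0.20-0.39 weak, 0.40-0.59 moderate, 0.60-0.79
#' strong, 0.80-1 very strong.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return A tibble `rho`, `band`, `n` (rho NA with a warning for constant
#'   input).
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector; correlation undefined", call. = FALSE)
    return(tibble::tibble(rho = NA_real_, band = NA_character_,
                          n = length(x)))
  }
  rho <- cor(x, y, method = "spearman")
  tibble::tibble(rho = rho, band = correlation_band(rho), n = length(x))
}

#' @rdname spearman_correlation
#' @param rho Correlation coefficient(s).
#' @export
correlation_band <- function(rho) {
  a <- abs(rho)
  dplyr::case_when(
    is.na(a) ~ NA_character_,
    a < 0.20 ~ "very weak",
    a < 0.40 ~ "weak",
    a < 0.60 ~ "moderate",
    a < 0.80 ~ "strong",
    TRUE ~ "very strong")
}

#' Bonferroni-corrected significance level
#'
#' `alpha = 0.05 / n`, rounded to 4 decimals for reporting: 9 comparisons
#' give 0.0056, 20 give 0.0025.
#'
#' @param n_comparisons Number of comparisons (>= 1).
#' @return The corrected alpha.
#' @export
significance_levels <- function(n_comparisons) {
  if (any(n_comparisons < 1)) stop("n_comparisons must be >= 1", call. = FALSE)
  round(0.05 / n_comparisons, 4)
}

#' Paired and unpaired rank comparisons
#'
#' Thin wrappers around the exact Wilcoxon signed-rank and Mann-Whitney U
#' tests (exact null distributions for small samples without ties, normal
#' approximation otherwise), returned tidily.
#'
#' @param x,y Numeric vectors (paired and equal length for the signed-rank
#'   test).
#' @return A tibble `statistic`, `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  w <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  tibble::tibble(statistic = unname(w$statistic), p_value = w$p.value,
                 method = "wilcoxon_signed_rank")
}

#' @rdname wilcoxon_signed_rank
#' @export
mann_whitney_u <- function(x, y) {
  w <- suppressWarnings(wilcox.test(x, y))
  tibble::tibble(statistic = unname(w$statistic), p_value = w$p.value,
                 method = "mann_whitney_u")
}

#' Exclusion ledger of a record table
#'
#' Per parameter: total records, retained, and excluded-by-reason counts;
#' retained plus the per-reason counts always equal the total.
#'
#' @param records Muscle-record tibble.
#' @return A tibble `parameter`, `total`, `retained`, plus one row per
#'   exclusion reason in long form (`reason`, `n`).
#' @export
records_ledger <- function(records) {
  records |>
    dplyr::group_by(.data$parameter, .data$reason) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(total = sum(.data$n),
                  retained = sum(.data$n[.data$reason == "none"])) |>
    dplyr::ungroup()
}

#' Export the long-format record table
#'
#' Writes the muscle records as a tidy CSV (one record per row, stable column
#' order) with a JSON ledger summary alongside, ready for external
#' mixed-model fitting.
#'
#' @param records Muscle-record tibble.
#' @param path Output CSV path; the ledger is written to
#'   `<path>.ledger.json`.
#' @return `path`, invisibly.
#' @export
export_long_table <- function(records, path) {
  cols <- c("subject", "group", "visit", "side", "muscle", "compartment",
            "parameter", "mean_value", "n_voxels", "excluded", "reason")
  extra <- setdiff(names(records), cols)
  records <- records[, c(intersect(cols, names(records)), extra)]
  readr::write_csv(records, path)
  ledger <- records_ledger(records)
  jsonlite::write_json(ledger, paste0(path, ".ledger.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_long_table
#' @return For `read_long_table`, the records tibble.
#' @export
read_long_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = readr::col_character(),
                    visit = readr::col_character(),
                    side = readr::col_character(),
                    muscle = readr::col_character()))
}
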