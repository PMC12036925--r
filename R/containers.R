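#' Multi-volume acquisition with per-volume metadata
#'
#' A light container for a stack of image volumes acquired under varying
#' acquisition settings (echo time, readout shift, diffusion gradient, mixing
#' time). The voxel data live in a single 4D array `[nx, ny, nz, nvol]`
#' (complex or double depending on the modality) and one metadata row per
#' volume describes how that volume was acquired.
#'
#' @param data 4D array, last dimension indexing volumes.
#' @param meta A data frame with one row per volume (columns depend on the
#'   modality, e.g. `te_ms`, `shift_ms`, `bval`, `gx/gy/gz`, `tm_ms`).
#' @param modality Character scalar, e.g. `"dixon"`, `"mse"`, `"dti"`,
#'   `"fingerprint"`.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param extra Named list of modality-level metadata (e.g. `fat_hz`).
#' @return An object of class `acquisition_series`.
#' @export
acquisition_series <- function(data, meta, modality, spacing = c(1, 1, 5),
                               extra = list()) {
  stopifnot(length(dim(data)) == 4L)
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != dim(data)[4])
    stop("meta must have one row per volume", call. = FALSE)
  structure(
    list(data = data, meta = meta, modality = modality,
         spacing = as.numeric(spacing), extra = extra),
    class = "acquisition_series"
  )
}

#' @export
print.acquisition_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<acquisition_series: %s>\n", x$modality))
  cat(sprintf("  grid %d x %d x %d, %d volumes (%s)\n", d[1], d[2], d[3], d[4],
              if (is.complex(x$data)) "complex" else "real"))
  cat(sprintf("  spacing %s mm\n", paste(signif(x$spacing, 3), collapse = " x ")))
  print(head(x$meta, 4))
  invisible(x)
}

#' @export
dim.acquisition_series <- function(x) dim(x$data)

#' Per-voxel scalar parameter map with validity mask and exclusion reasons
#'
#' Holds one quantitative parameter per voxel (FF in percent, T2/T1 in ms, MD
#' in um^2/ms, FA dimensionless, ...) together with a logical validity mask and
#' a per-voxel exclusion reason code. Voxels can be invalid either because the
#' parameter is undefined there (zero signal) or because a quality rule
#' excluded them; downstream ROI aggregation only averages valid voxels and
#' keeps the ledger of reasons.
#'
#' @param values Numeric 3D array of parameter values (NA where undefined).
#' @param mask Logical array of the same dimension; `TRUE` = valid.
#' @param parameter Name of the parameter (e.g. `"ff"`, `"water_t2"`).
#' @param unit Unit string (e.g. `"%"`, `"ms"`).
#' @param reason Character array of exclusion reason codes; `"none"` where the
#'   voxel is valid. Defaults to all-`"none"`/`"undefined"` from `mask`.
#' @return An object of class `quantitative_map`.
#' @export
quantitative_map <- function(values, mask = !is.na(values), parameter = "value",
                             unit = "", reason = NULL) {
  stopifnot(length(dim(values)) == 3L, all(dim(values) == dim(mask)))
  if (is.null(reason)) {
    reason <- array("none", dim(values))
    reason[!mask] <- "undefined"
  }
  stopifnot(all(dim(reason) == dim(values)))
  structure(list(values = values, mask = mask, reason = reason,
                 parameter = parameter, unit = unit),
            class = "quantitative_map")
}

#' @export
print.quantitative_map <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[x$mask]
  cat(sprintf("<quantitative_map: %s [%s]> %d x %d x %d\n",
              x$parameter, x$unit, d[1], d[2], d[3]))
  cat(sprintf("  %d valid voxels (%.1f%%)", sum(x$mask),
              100 * mean(x$mask)))
  if (length(v))
    cat(sprintf("; range %.3g .. %.3g, median %.3g", min(v), max(v), median(v)))
  cat("\n")
  tab <- table(x$reason[!x$mask])
  if (length(tab))
    cat("  exclusions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  invisible(x)
}

#' Exclude voxels from a quantitative map with a reason code
#'
#' Applies a logical exclusion to a map, recording `reason` for the newly
#' excluded voxels. Already-invalid voxels keep their original reason
#' (exclusion is idempotent and never overwrites an earlier code).
#'
#' @param map A [quantitative_map].
#' @param exclude Logical array, `TRUE` where voxels must be excluded.
#' @param reason Single reason code string.
#' @return The updated [quantitative_map].
#' @export
exclude_voxels <- function(map, exclude, reason) {
  stopifnot(inherits(map, "quantitative_map"),
            all(dim(exclude) == dim(map$values)))
  newly <- exclude & map$mask
  map$mask[newly] <- FALSE
  map$reason[newly] <- reason
  map
}

#' Summarise a map's voxel ledger
#'
#' @param map A [quantitative_map].
#' @return A tibble with one row per reason code (including `"none"` for
#'   retained voxels) and the voxel count; counts always sum to the total
#'   number of voxels.
#' @export
map_ledger <- function(map) {
  stopifnot(inherits(map, "quantitative_map"))
  tab <- table(map$reason)
  tibble::tibble(reason = names(tab), voxels = as.integer(tab))
}
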