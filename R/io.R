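#' Read a lens catalog from CSV
#'
#' Schema: header `name,cylinder_iol_plane_D,sphere_min_D,sphere_max_D,a_constant`,
#' comma-separated, `.` decimal. Malformed rows are rejected with the row
#' number and offending field; an empty body yields an empty catalog with a
#' warning.
#'
#' @param path path to the CSV file.
#' @return A [lens_catalog()].
#' @examples
#' read_catalog(system.file("extdata", "alcon_acrysof.csv", package = "toricity"))
#' @export
read_catalog <- function(path) {
  if (!file.exists(path))
    stop_toricity(paste("catalog file not found:", path), "toricity_io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "cylinder_iol_plane_D", "sphere_min_D", "sphere_max_D",
            "a_constant")
  if (!identical(names(df), need))
    stop_toricity(paste("catalog header must be:", paste(need, collapse = ",")),
                  "toricity_io")
  num <- need[-1]
  for (i in seq_len(nrow(df))) for (f in num) {
    if (!is.numeric(df[[f]]) || !is.finite(df[[f]][i]))
      stop_toricity(sprintf("catalog row %d: field %s is not a number", i, f),
                    "toricity_io")
  }
  if (nrow(df) == 0) warning("empty lens catalog", call. = FALSE)
  lens_catalog(df)
}

#' Shipped default catalogs
#'
#' Editable defaults for the three lens families used in the worked
#' examples. Cylinder powers that were printed in a calculator's output
#' (SN6AT8 5.25 D; ZCT450/525/600 4.50/5.25/6.00 D) are authoritative; the
#' remaining rows, the sphere ranges (deliberately wide, 0--40 D, so the
#' default probe grid is fully covered) and the A-constants (calibrated, see
#' the methods vignette) are synthetic defaults meant to be edited. The
#' enVista MX60T cylinder lineup in particular is a synthetic placeholder:
#' no MX60T cylinder power appears in any probed output.
#'
#' @param name one of `"alcon_acrysof"`, `"abbott_tecnis"`,
#'   `"bausch_envista"`.
#' @return A [lens_catalog()].
#' @export
default_catalog <- function(name = c("alcon_acrysof", "abbott_tecnis",
                                     "bausch_envista")) {
  name <- match.arg(name)
  read_catalog(system.file("extdata", paste0(name, ".csv"),
                           package = "toricity", mustWork = TRUE))
}

#' Write / read a toricity matrix
#'
#' CSV layout mirrors the published tables: first column `mean_k_D`
#' (descending), remaining columns named by axial length (ascending), cells
#' at full precision with invalid cells rendered `NA`. JSON serializes the
#' full object (values, axes, provenance, classification) losslessly.
#'
#' @param matrix a [toricity_matrix()].
#' @param path output path; format inferred from the extension when
#'   `format` is `NULL`.
#' @param format `"csv"` or `"json"`.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   the reconstructed [toricity_matrix()].
#' @export
write_matrix <- function(matrix, path, format = NULL) {
  stopifnot(inherits(matrix, "toricity_matrix"))
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- data.frame(mean_k_D = rownames(matrix$values),
                     matrix$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    obj <- list(values = unname(matrix$values),
                mean_ks_desc = as.numeric(rownames(matrix$values)),
                axial_lengths = as.numeric(colnames(matrix$values)),
                classification = matrix$classification,
                constant_value = matrix$constant_value,
                tolerance = matrix$tolerance,
                provenance = matrix$provenance)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    values <- as.matrix(df[, -1, drop = FALSE])
    rownames(values) <- as.character(df$mean_k_D)
    toricity_matrix(values)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    values <- obj$values
    storage.mode(values) <- "double"
    dimnames(values) <- list(as.character(obj$mean_ks_desc),
                             as.character(obj$axial_lengths))
    prov <- obj$provenance
    if (!is.null(prov)) prov <- as.data.frame(prov, stringsAsFactors = FALSE)
    toricity_matrix(values, provenance = prov,
                    tolerance = obj$tolerance %||% 0.02)
  }
}

#' Read a tabulated toricity surface from CSV
#'
#' Same layout as the matrix CSV ([write_matrix()]): `mean_k_D` rows
#' descending, AL columns ascending. Returned as a `"table"`
#' [toricity_model()].
#'
#' @param path CSV path.
#' @return A [toricity_model()] of kind `"table"`.
#' @export
read_tau_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mk_desc <- as.numeric(df$mean_k_D)
  als <- as.numeric(names(df)[-1])
  values <- as.matrix(df[, -1, drop = FALSE])
  ord <- order(mk_desc)  # ascending for the interpolator
  toricity_model("table", axial_lengths = als, mean_ks = mk_desc[ord],
                 values = values[ord, , drop = FALSE])
}

#' A calculator interface backed by hand-transcribed outputs
#'
#' To probe a real web calculator, a user runs each grid cell by hand and
#' records the outputs in a CSV with columns `axial_length_mm`, `mean_k_D`,
#' `name`, `cylinder_iol_plane_D`, `residual_D`, `residual_axis_deg` (one
#' row per recommended lens per cell). This wraps that transcript in the
#' same interface as [simulated_calculator()].
#'
#' @param transcript a data frame with the columns above, or a CSV path.
#' @return A function of a [biometry_case()] suitable for [probe()].
#' @export
transcript_calculator <- function(transcript) {
  if (is.character(transcript))
    transcript <- utils::read.csv(transcript, stringsAsFactors = FALSE)
  need <- c("axial_length_mm", "mean_k_D", "name", "cylinder_iol_plane_D",
            "residual_D", "residual_axis_deg")
  missing_cols <- setdiff(need, names(transcript))
  if (length(missing_cols))
    stop_toricity(paste("transcript lacks columns:",
                        paste(missing_cols, collapse = ", ")),
                  "toricity_io")
  function(case) {
    hit <- abs(transcript$axial_length_mm - case$axial_length) < 1e-6 &
      abs(transcript$mean_k_D - mean_k(case)) < 1e-6
    transcript[hit, c("name", "cylinder_iol_plane_D", "residual_D",
                      "residual_axis_deg"), drop = FALSE]
  }
}

#' Emit the worked examples as ready-to-run extraction CSVs
#'
#' Writes the two fully printed example calculations -- the Alcon SN6AT8
#' case and the three Abbott Tecnis lenses -- in the batch-extraction schema
#' of [batch_extract()]. (The third, enVista, example cannot be emitted: its
#' lens cylinder power was never displayed, only the resulting ratio 1.43.)
#'
#' @param dir output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_fixtures <- function(dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alcon <- data.frame(lens = "SN6AT8", lens_cyl_D = 5.25, cross_cyl_D = 4.00,
                      steep_axis_deg = 90, residual_D = 0.40,
                      residual_axis_deg = 90)
  abbott <- data.frame(lens = c("ZCT450", "ZCT525", "ZCT600"),
                       lens_cyl_D = c(4.50, 5.25, 6.00), cross_cyl_D = 4.00,
                       steep_axis_deg = 90,
                       residual_D = c(0.58, 0.04, 0.50),
                       residual_axis_deg = c(90, 90, 0))
  p1 <- file.path(dir, "example_alcon_acrysof.csv")
  p2 <- file.path(dir, "example_abbott_tecnis.csv")
  utils::write.csv(alcon, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(abbott, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
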