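# Long-format measurement tables: one row per (subject, side, reader,
# modality) cell, angle in degrees, missing cells as NA.

#' Validate / construct a measurement table
#'
#' A measurement table is a long-format tibble with columns `subject`, `side`
#' (`"right"`/`"left"`), `reader`, `modality` and `angle_deg`. Keys must be
#' unique; `angle_deg` may be `NA` for missing cells but must otherwise be
#' finite.
#'
#' @param data A data frame with the columns above.
#' @return A validated tibble.
#' @export
as_measurement_table <- function(data) {
  req <- c("subject", "side", "reader", "modality", "angle_deg")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("measurement table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "femtor_error_schema")
  }
  tb <- tibble::as_tibble(data)
  tb$subject <- as.character(tb$subject)
  tb$side <- as.character(tb$side)
  tb$reader <- as.character(tb$reader)
  tb$modality <- as.character(tb$modality)
  tb$angle_deg <- as.numeric(tb$angle_deg)
  bad_side <- which(!tb$side %in% c("right", "left"))
  if (length(bad_side) > 0L) {
    abort(sprintf("invalid side '%s' in measurement table row %d",
                  tb$side[bad_side[1]], bad_side[1]),
          class = "femtor_error_schema")
  }
  bad <- which(!is.na(tb$angle_deg) & !is.finite(tb$angle_deg))
  if (length(bad) > 0L) {
    abort(sprintf("non-finite angle in measurement table row %d", bad[1]),
          class = "femtor_error_schema")
  }
  keys <- paste(tb$subject, tb$side, tb$reader, tb$modality)
  if (anyDuplicated(keys)) {
    abort(sprintf("duplicate (subject, side, reader, modality) key in row %d",
                  which(duplicated(keys))[1]),
          class = "femtor_error_schema")
  }
  tb[req]
}

#' Read/write measurement tables as CSV
#'
#' @param path CSV path with columns `subject,side,reader,modality,angle_deg`.
#' @param table A measurement table.
#' @return `read_measurement_table()` returns a validated tibble;
#'   `write_measurement_table()` returns `path` invisibly.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("measurement table not found: %s", path),
          class = "femtor_error_io")
  }
  as_measurement_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_measurement_table
#' @export
write_measurement_table <- function(table, path) {
  utils::write.csv(as_measurement_table(table), path, row.names = FALSE)
  invisible(path)
}

#' Simulate a reader/modality measurement table
#'
#' Draws torsion angles for `n_subjects` hips measured by two readers on two
#' modalities (CT and MRI) from the additive model
#' `y = mu + s_i + delta * [modality == MRI] + r_ij + e`, with subject effects
#' `s_i ~ N(0, sigma_s^2)`, reader-within-subject effects
#' `r_ij ~ N(0, sigma_r^2)` (shared across modalities), residuals
#' `e ~ N(0, sigma_e^2)`, and an MRI bias `delta`. Cells are then deleted
#' independently with probability `missing_prob`.
#'
#' @param n_subjects Number of subjects (one hip each).
#' @param mu True mean torsion (degrees).
#' @param sigma_s,sigma_r,sigma_e Between-subject, reader and residual
#'   standard deviations (degrees, >= 0).
#' @param delta MRI minus CT bias (degrees).
#' @param missing_prob Probability a cell is missing.
#' @param seed Integer seed.
#' @return A measurement table tibble (see [as_measurement_table()]).
#' @export
#' @examples
#' simulate_measurement_table(n_subjects = 5, seed = 7)
simulate_measurement_table <- function(n_subjects, mu = 10, sigma_s = 9,
                                       sigma_r = 0, sigma_e = 2, delta = 0,
                                       missing_prob = 0, seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("n_subjects must be >= 1", class = "femtor_error_parameter")
  }
  if (any(c(sigma_s, sigma_r, sigma_e) < 0)) {
    abort("standard deviations must be >= 0", class = "femtor_error_parameter")
  }
  if (missing_prob < 0 || missing_prob > 1) {
    abort("missing_prob must be in [0, 1]", class = "femtor_error_parameter")
  }
  n_subjects <- as.integer(n_subjects)
  withr::with_seed(as.integer(seed), {
    s <- rnorm(n_subjects, 0, sigma_s)
    grid <- tidyr::expand_grid(
      subject = sprintf("S%03d", seq_len(n_subjects)),
      reader = c("1", "2"),
      modality = c("CT", "MRI"))
    r_eff <- rnorm(n_subjects * 2L, 0, sigma_r)   # subject x reader
    names(r_eff) <- paste(rep(sprintf("S%03d", seq_len(n_subjects)), each = 2L),
                          rep(c("1", "2"), n_subjects))
    grid$angle_deg <- mu + s[match(grid$subject, sprintf("S%03d", seq_len(n_subjects)))] +
      delta * (grid$modality == "MRI") +
      r_eff[paste(grid$subject, grid$reader)] +
      rnorm(nrow(grid), 0, sigma_e)
    if (missing_prob > 0) {
      grid$angle_deg[runif(nrow(grid)) < missing_prob] <- NA_real_
    }
  })
  grid$side <- "right"
  as_measurement_table(grid[, c("subject", "side", "reader", "modality", "angle_deg")])
}
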