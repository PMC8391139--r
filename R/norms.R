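#' Construct a norm table
#'
#' Holds the configurable reference norms the binarization needs: the
#' regression-scale weight norms by height interval (mean `M` and the
#' regression sigma `delta_R`, both kg) and the breath-hold norms (seconds)
#' by age bracket for the Stange (post-inhalation) and Genchi
#' (post-exhalation) tests. All intervals are half-open `[min, max)`, must
#' be sorted and non-overlapping.
#'
#' National physical-development standards vary by country and revision, so
#' the package treats them as runtime configuration rather than constants;
#' [default_norms()] ships a synthetic, documented stand-in for testing.
#'
#' @param weight_norms data frame with columns `min_height`, `max_height`
#'   (cm), `M`, `delta_R` (kg).
#' @param stange_norm,genchi_norm data frames with columns `min_age`,
#'   `max_age` (years), `value` (seconds).
#' @return An object of class `norm_table`.
#' @export
norm_table <- function(weight_norms, stange_norm, genchi_norm) {
  weight_norms <- as.data.frame(weight_norms)
  stange_norm <- as.data.frame(stange_norm)
  genchi_norm <- as.data.frame(genchi_norm)
  stopifnot(all(c("min_height", "max_height", "M", "delta_R") %in%
                  names(weight_norms)),
            all(c("min_age", "max_age", "value") %in% names(stange_norm)),
            all(c("min_age", "max_age", "value") %in% names(genchi_norm)))
  check_intervals(weight_norms$min_height, weight_norms$max_height,
                  "weight_norms")
  check_intervals(stange_norm$min_age, stange_norm$max_age, "stange_norm")
  check_intervals(genchi_norm$min_age, genchi_norm$max_age, "genchi_norm")
  if (any(weight_norms$delta_R <= 0))
    stop("delta_R must be positive in every weight-norm interval",
         call. = FALSE)
  structure(list(weight_norms = weight_norms, stange_norm = stange_norm,
                 genchi_norm = genchi_norm),
            class = "norm_table")
}

check_intervals <- function(lo, hi, what) {
  if (any(hi <= lo))
    stop(sprintf("%s: empty or inverted interval", what), call. = FALSE)
  if (is.unsorted(lo, strictly = TRUE) || any(utils::head(hi, -1) > lo[-1]))
    stop(sprintf("%s: intervals must be sorted and non-overlapping", what),
         call. = FALSE)
  invisible(TRUE)
}

lookup_interval <- function(lo, hi, x, what) {
  i <- which(lo <= x & x < hi)
  if (length(i) != 1L)
    stop(sprintf("%s = %s falls outside the covered intervals [%s, %s)",
                 what, x, min(lo), max(hi)), call. = FALSE)
  i
}

lookup_weight_norm <- function(norms, body_length) {
  stopifnot(inherits(norms, "norm_table"))
  w <- norms$weight_norms
  i <- lookup_interval(w$min_height, w$max_height, body_length, "body_length")
  list(M = w$M[i], delta_R = w$delta_R[i])
}

lookup_age_norm <- function(norms, age, test = c("stange", "genchi")) {
  stopifnot(inherits(norms, "norm_table"))
  test <- match.arg(test)
  a <- norms[[paste0(test, "_norm")]]
  a$value[lookup_interval(a$min_age, a$max_age, age, "age")]
}

#' Synthetic default norm table
#'
#' A plausible, synthetic stand-in for national schoolchildren
#' physical-development standards, covering heights 125-170 cm and ages
#' 5-25 years. Values are fixture choices on the scale of published norms
#' for school-age girls, not any country's official table; replace with
#' [read_norms()] for real use.
#'
#' @return A [norm_table()].
#' @examples
#' default_norms()
#' @export
default_norms <- function() {
  norm_table(
    weight_norms = data.frame(
      min_height = seq(125, 165, by = 5),
      max_height = seq(130, 170, by = 5),
      M = c(27, 30, 33, 36.5, 40, 43.5, 47, 51, 55),
      delta_R = c(3.8, 4.0, 4.3, 4.6, 4.9, 5.2, 5.6, 6.0, 6.4)),
    stange_norm = data.frame(
      min_age = c(5, 7, 9, 11, 13, 15, 18),
      max_age = c(7, 9, 11, 13, 15, 18, 25),
      value = c(20, 30, 40, 48, 55, 60, 65)),
    genchi_norm = data.frame(
      min_age = c(5, 7, 9, 11, 13, 15, 18),
      max_age = c(7, 9, 11, 13, 15, 18, 25),
      value = c(12, 16, 20, 24, 28, 30, 32))
  )
}

#' Read a norm table from YAML or JSON
#'
#' Expects keys `weight_norms` (list of `{min_height, max_height, M,
#' delta_R}`) and `stange_norm`, `genchi_norm` (lists of `{min_age,
#' max_age, value}`); intervals half-open `[min, max)`.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [norm_table()].
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("norms file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  to_df <- function(x) do.call(rbind, lapply(x, as.data.frame))
  as_df <- function(x) if (is.data.frame(x)) x else to_df(x)
  norm_table(weight_norms = as_df(raw$weight_norms),
             stange_norm = as_df(raw$stange_norm),
             genchi_norm = as_df(raw$genchi_norm))
}

#' @export
print.norm_table <- function(x, ...) {
  cat("Norm table:\n")
  cat(sprintf("  weight norms: %d height intervals [%g, %g) cm\n",
              nrow(x$weight_norms), min(x$weight_norms$min_height),
              max(x$weight_norms$max_height)))
  cat(sprintf("  Stange/Genchi norms: %d age brackets [%g, %g) y\n",
              nrow(x$stange_norm), min(x$stange_norm$min_age),
              max(x$stange_norm$max_age)))
  invisible(x)
}
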