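#' Read an accession-level climate table
#'
#' Delimited text with a header row; the delimiter is taken from the file
#' extension (`.tsv`/`.txt` = tab, otherwise comma). One row per accession.
#' A column `otu_id` is required; bioclim columns are matched
#' case-insensitively against `bio1`..`bio19` and renamed to lower case.
#' Missing values stay `NA` — they are never treated as zero.
#'
#' @param file Path to the table.
#' @return A data.frame with `otu_id`, any `bio*` columns found, and
#'   optional `lat`/`lon`.
#' @export
read_accessions <- function(file) {
  sep <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  names(df) <- ifelse(grepl("^bio[0-9]+$", names(df), ignore.case = TRUE) |
                        tolower(names(df)) %in% c("otu_id", "lat", "lon"),
                      tolower(names(df)), names(df))
  if (!"otu_id" %in% names(df))
    stop("accession table must contain an 'otu_id' column", call. = FALSE)
  if (any(!nzchar(df$otu_id)) || anyNA(df$otu_id))
    stop("empty otu_id values in accession table", call. = FALSE)
  biocols <- grep("^bio[0-9]+$", names(df), value = TRUE)
  if (!length(biocols))
    stop("accession table contains no bio1..bio19 columns", call. = FALSE)
  df
}

#' Per-OTU summary of one climate variable
#'
#' Collapses accession-level records to one row per OTU with the mean, min,
#' max and count of non-missing values. Rows missing the variable are
#' dropped for that variable only (with a message), not for the whole OTU.
#'
#' @param records Accession data.frame (see [read_accessions()]).
#' @param variable Column name, e.g. `"bio1"`.
#' @return data.frame with `otu_id`, `variable`, `mean`, `min`, `max`, `n`.
#' @export
summarize_by_otu <- function(records, variable) {
  if (!variable %in% names(records))
    stop("variable '", variable, "' not found in records", call. = FALSE)
  v <- records[[variable]]
  keep <- !is.na(v)
  if (!any(keep))
    stop("no usable (non-missing) records for variable '", variable, "'",
         call. = FALSE)
  if (any(!keep))
    message(sum(!keep), " record(s) with missing '", variable, "' dropped")
  otu <- records$otu_id[keep]
  v <- v[keep]
  sp <- split(v, otu)
  out <- data.frame(
    otu_id = names(sp),
    variable = variable,
    mean = vapply(sp, mean, numeric(1)),
    min = vapply(sp, min, numeric(1)),
    max = vapply(sp, max, numeric(1)),
    n = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Pooled-variance sampling errors per OTU
#'
#' Many OTUs are represented by a single accession, so a per-OTU sample
#' variance is unavailable. The pooled variance across all OTUs with
#' n >= 2,
#' `s_p^2 = sum((n_i - 1) * s_i^2) / sum(n_i - 1)`,
#' supplies a common within-OTU spread, and each OTU's sampling error is
#' `se_i = s_p / sqrt(n_i)` (default). The literal alternative
#' `s_p^2 / sqrt(n_i)` — pooled *variance* over root sample size — is
#' available via `formula = "var_over_sqrt_n"` for reproducing analyses
#' that used it, although it is not dimensionally a standard error.
#'
#' @param records Accession data.frame.
#' @param variable Column name.
#' @param formula `"sd_over_sqrt_n"` (default) or `"var_over_sqrt_n"`.
#' @return data.frame with `otu_id`, `n`, `se`; attribute `pooled_var`
#'   holds s_p^2.
#' @export
pooled_se <- function(records, variable,
                      formula = c("sd_over_sqrt_n", "var_over_sqrt_n")) {
  formula <- match.arg(formula)
  summ <- suppressMessages(summarize_by_otu(records, variable))
  v <- records[[variable]]
  keep <- !is.na(v)
  sp <- split(v[keep], records$otu_id[keep])
  ni <- vapply(sp, length, integer(1))
  if (all(ni < 2))
    stop("all OTUs are singletons for '", variable,
         "': pooled variance is undefined; supply se explicitly or set se = 0",
         call. = FALSE)
  multi <- ni >= 2
  s2 <- vapply(sp[multi], stats::var, numeric(1))
  pooled <- sum((ni[multi] - 1) * s2) / sum(ni[multi] - 1)
  num <- if (formula == "sd_over_sqrt_n") sqrt(pooled) else pooled
  out <- data.frame(otu_id = names(sp), n = ni, se = num / sqrt(ni),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pooled_var") <- pooled
  out
}

#' Tidy per-OTU trait summary across variables
#'
#' Combines [summarize_by_otu()] and [pooled_se()] into the long-format
#' table (otu_id, variable, mean, min, max, n, se) consumed by the analysis
#' stages and written by the pipeline.
#'
#' @param records Accession data.frame.
#' @param variables Character vector of columns; default all `bio*` columns.
#' @param se_formula Passed to [pooled_se()].
#' @return Long data.frame, one row per (otu_id, variable).
#' @export
trait_summary <- function(records, variables = NULL,
                          se_formula = c("sd_over_sqrt_n",
                                         "var_over_sqrt_n")) {
  se_formula <- match.arg(se_formula)
  if (is.null(variables))
    variables <- grep("^bio[0-9]+$", names(records), value = TRUE)
  out <- lapply(variables, function(v) {
    s <- suppressMessages(summarize_by_otu(records, v))
    e <- pooled_se(records, v, formula = se_formula)
    s$se <- e$se[match(s$otu_id, e$otu_id)]
    s
  })
  do.call(rbind, out)
}

#' Extract a named tip vector for one variable from a trait summary
#'
#' @param summary Output of [trait_summary()].
#' @param variable Variable name.
#' @param value One of `"mean"`, `"min"`, `"max"`, `"se"`.
#' @return Named numeric vector (names = otu_id).
#' @export
trait_vector <- function(summary, variable,
                         value = c("mean", "min", "max", "se")) {
  value <- match.arg(value)
  rows <- summary[summary$variable == variable, ]
  if (!nrow(rows)) stop("variable '", variable, "' not in summary",
                        call. = FALSE)
  stats::setNames(rows[[value]], rows$otu_id)
}

#' Default bioclim variable grouping
#'
#' The six climatic variable groups used to organize the 19 bioclim
#' variables: Groups 1–3 collect annual means and warm/cold (humid/dry)
#' extremes of temperature and specific humidity; Group 4 is temperature
#' seasonality and annual range; Group 5 humidity seasonality; Group 6
#' isothermality. The diurnal-range variable bio2 is left ungrouped.
#'
#' @return Named character vector mapping `bio1`..`bio19` to group labels.
#' @export
default_variable_groups <- function() {
  g <- c(bio1 = "1", bio12 = "1",
         bio5 = "2", bio8 = "2", bio10 = "2", bio13 = "2", bio16 = "2",
         bio18 = "2",
         bio6 = "3", bio9 = "3", bio11 = "3", bio14 = "3", bio17 = "3",
         bio19 = "3",
         bio4 = "4", bio7 = "4",
         bio15 = "5",
         bio3 = "6",
         bio2 = "ungrouped")
  g[paste0("bio", 1:19)]
}

#' Read a variable-group configuration
#'
#' YAML or JSON mapping of variable name to group label. Every bio variable
#' must appear exactly once.
#'
#' @param file Path to a YAML/JSON mapping.
#' @return Named character vector.
#' @export
read_variable_groups <- function(file) {
  m <- yaml::read_yaml(file)
  g <- vapply(m, as.character, character(1))
  if (anyDuplicated(names(g)))
    stop("duplicate variable in group config", call. = FALSE)
  g
}
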