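#' Read a quantified metabolite concentration table
#'
#' Reads a samples-by-metabolites concentration table such as the export of a
#' Chenomx-style profiling of \eqn{^1}H NMR spectra. The first column must
#' hold sample identifiers and the header row metabolite names; the body is
#' numeric concentrations in mM.
#'
#' @param path Path to a CSV or TSV file.
#' @param dialect `"csv"` (default) or `"tsv"`.
#'
#' @return A tibble whose first column is `sample_id` (character) followed by
#'   one numeric column per metabolite, in file order.
#'
#' @details Missing, `NA` or non-numeric cells are an error that names the
#'   offending sample and metabolite; duplicated metabolite names are an
#'   error. Values must be finite and non-negative.
#'
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines("sample_id,glycine,choline\ns1,1.2,0.4\ns2,1.5,0.5", path)
#' read_concentration_table(path)
#' @export
read_concentration_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  raw <- suppressMessages(
    reader(path, col_types = readr::cols(.default = readr::col_character()),
           name_repair = "minimal", progress = FALSE))
  if (ncol(raw) < 2) stop("concentration table needs a sample-id column and at least one metabolite", call. = FALSE)
  mets <- names(raw)[-1]
  if (anyDuplicated(mets)) {
    stop("duplicated metabolite name(s): ",
         paste(unique(mets[duplicated(mets)]), collapse = ", "), call. = FALSE)
  }
  ids <- as.character(raw[[1]])
  out <- tibble::tibble(sample_id = ids)
  for (m in mets) {
    cell <- raw[[m]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or missing concentration at sample '%s', metabolite '%s'",
                   ids[bad[1]], m), call. = FALSE)
    }
    if (any(num < 0)) {
      stop(sprintf("negative concentration at sample '%s', metabolite '%s'",
                   ids[which(num < 0)[1]], m), call. = FALSE)
    }
    out[[m]] <- num
  }
  out
}

#' Write a concentration table
#'
#' Writes with 17 significant digits so that a write/read round trip is
#' bit-exact.
#'
#' @param table A concentration tibble as returned by
#'   [read_concentration_table()] or [simulate_cohort()].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  stopifnot(names(table)[1] == "sample_id")
  chr <- table
  for (m in names(chr)[-1]) chr[[m]] <- sprintf("%.17g", table[[m]])
  lines <- c(paste(names(chr), collapse = sep),
             apply(as.matrix(chr), 1, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path CSV with columns `sample_id`, `sex`, `age_years`, `pmi_hours`,
#'   `cause_of_death` and optionally `protocol`.
#' @return A tibble with those columns; `sample_id` character, `sex` one of
#'   `"M"`/`"F"`, ages and PMIs positive numerics.
#' @export
read_metadata <- function(path) {
  md <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    sex = readr::col_character(),
    age_years = readr::col_double(),
    pmi_hours = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  req <- c("sample_id", "sex", "age_years", "pmi_hours")
  miss <- setdiff(req, names(md))
  if (length(miss) > 0) stop("metadata missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(md$sample_id)) stop("duplicated sample_id in metadata", call. = FALSE)
  if (!all(md$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'", call. = FALSE)
  if (any(!is.finite(md$age_years)) || any(md$age_years <= 0)) stop("age_years must be positive", call. = FALSE)
  if (any(!is.finite(md$pmi_hours)) || any(md$pmi_hours <= 0)) stop("pmi_hours must be positive", call. = FALSE)
  invisible(md)
}

#' The 24-autopsy pericardial-fluid cohort
#'
#' Demographic and thanatological metadata of the 24 consecutive judicial
#' autopsies in which pericardial fluid was sampled: sex, age (20--87 years),
#' PMI (16--170 hours) and cause of death.
#'
#' @return A 24-row tibble with columns `sample_id`, `sex`, `age_years`,
#'   `pmi_hours`, `cause_of_death`, `protocol` (`"untreated"`: the cohort
#'   metadata are per individual, before any protein-removal protocol).
#' @examples
#' cohort <- load_cohort_fixture()
#' cohort_summary(cohort)
#' @export
load_cohort_fixture <- function() {
  path <- system.file("extdata", "cohort24_fixture.csv", package = "pfpmi", mustWork = TRUE)
  md <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    sex = readr::col_character(),
    age_years = readr::col_double(),
    pmi_hours = readr::col_double(),
    cause_of_death = readr::col_character()
  ), progress = FALSE)
  md$protocol <- "untreated"
  validate_metadata(md)
  md
}

#' Cohort summary statistics
#'
#' Mean and standard deviation (n - 1 denominator) of age and PMI, the sex
#' split and the Pearson correlation between PMI and age with its two-sided
#' test p-value.
#'
#' @param metadata A metadata tibble (see [read_metadata()]).
#' @return A one-row tibble with columns `n`, `n_male`, `n_female`,
#'   `age_mean`, `age_sd`, `pmi_mean`, `pmi_sd`, `pmi_age_r`, `pmi_age_p`.
#' @export
cohort_summary <- function(metadata) {
  validate_metadata(metadata)
  ct <- cor.test(metadata$pmi_hours, metadata$age_years)
  tibble::tibble(
    n = nrow(metadata),
    n_male = sum(metadata$sex == "M"),
    n_female = sum(metadata$sex == "F"),
    age_mean = mean(metadata$age_years),
    age_sd = sd(metadata$age_years),
    pmi_mean = mean(metadata$pmi_hours),
    pmi_sd = sd(metadata$pmi_hours),
    pmi_age_r = unname(ct$estimate),
    pmi_age_p = ct$p.value
  )
}

#' Default exogenous metabolite exclusion list
#'
#' Ethanol and caffeine, the exogenous compounds named in the panel, plus any
#' panel name tagged as a drug.
#'
#' @param drugs Additional drug names to exclude (character vector).
#' @return Character vector of names matched case-insensitively by
#'   [exclude_exogenous()].
#' @export
default_exclusions <- function(drugs = character()) {
  unique(c("ethanol", "caffeine", drugs))
}

#' Remove exogenous metabolites from a concentration table
#'
#' Exogenous compounds (ethanol, caffeine, drugs) reflect exposure rather than
#' post-mortem biochemistry and are excluded before modelling. Matching is
#' case-insensitive; names on the list that are absent from the table are
#' ignored.
#'
#' @param table A concentration tibble.
#' @param exclusions Character vector of metabolite names to drop; defaults to
#'   [default_exclusions()].
#' @return The table without the excluded columns, other columns untouched
#'   and in the original order.
#' @export
exclude_exogenous <- function(table, exclusions = default_exclusions()) {
  stopifnot(names(table)[1] == "sample_id")
  mets <- names(table)[-1]
  drop <- mets[tolower(mets) %in% tolower(exclusions)]
  keep <- setdiff(mets, drop)
  if (length(keep) == 0) stop("empty panel: exclusion list removes every metabolite", call. = FALSE)
  table[, c("sample_id", keep)]
}

#' Autoscale a concentration table
#'
#' Mean-centres and scales each metabolite to unit variance (SD with the
#' n - 1 denominator), the standard pre-treatment that gives every metabolite
#' equal a-priori weight in multivariate modelling. With `reference` given,
#' applies that training set's centring/scaling statistics instead (test-set
#' projection).
#'
#' @param table A concentration tibble (first column `sample_id`) or a numeric
#'   matrix with sample row names.
#' @param reference Optional `pf_scaled` object whose statistics to apply.
#' @return A `pf_scaled` object: list with `values` (numeric matrix),
#'   `center`, `scale` (named vectors, mM), `sample_ids`, `metabolites`, and
#'   `dropped` (zero-variance columns removed before scaling, with a warning).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_samples = 12, seed = 1))
#' sc <- autoscale(cohort$tables$U)
#' colMeans(sc$values)   # ~ 0
#' @export
autoscale <- function(table, reference = NULL) {
  x <- conc_matrix(table)
  if (is.null(reference)) {
    if (nrow(x) < 2) stop("autoscaling needs at least 2 samples (or a reference)", call. = FALSE)
    sds <- apply(x, 2, sd)
    zero <- colnames(x)[sds < .Machine$double.eps^0.5]
    if (length(zero) > 0) {
      warning("dropping zero-variance metabolite(s): ", paste(zero, collapse = ", "),
              call. = FALSE)
      x <- x[, setdiff(colnames(x), zero), drop = FALSE]
    }
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    structure(list(
      values = scale(x, center = ctr, scale = scl)[, , drop = FALSE],
      center = ctr, scale = scl,
      sample_ids = rownames(x), metabolites = colnames(x), dropped = zero
    ), class = "pf_scaled")
  } else {
    stopifnot(inherits(reference, "pf_scaled"))
    miss <- setdiff(reference$metabolites, colnames(x))
    if (length(miss) > 0) stop("table lacks reference metabolite(s): ", paste(miss, collapse = ", "), call. = FALSE)
    x <- x[, reference$metabolites, drop = FALSE]
    structure(list(
      values = sweep(sweep(x, 2, reference$center), 2, reference$scale, "/"),
      center = reference$center, scale = reference$scale,
      sample_ids = rownames(x), metabolites = reference$metabolites,
      dropped = reference$dropped
    ), class = "pf_scaled")
  }
}

#' Invert autoscaling
#'
#' @param scaled A `pf_scaled` object.
#' @return The concentration matrix on the original mM scale.
#' @export
unscale <- function(scaled) {
  stopifnot(inherits(scaled, "pf_scaled"))
  sweep(sweep(scaled$values, 2, scaled$scale, "*"), 2, scaled$center, "+")
}

#' @export
print.pf_scaled <- function(x, ...) {
  cat("Autoscaled table:", nrow(x$values), "samples x", ncol(x$values), "metabolites\n")
  if (length(x$dropped) > 0) cat("dropped zero-variance:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

# concentration tibble (or matrix) -> numeric matrix with sample rownames
conc_matrix <- function(table) {
  if (is.matrix(table)) {
    storage.mode(table) <- "double"
    if (is.null(rownames(table))) rownames(table) <- paste0("s", seq_len(nrow(table)))
    return(table)
  }
  stopifnot(is.data.frame(table), names(table)[1] == "sample_id")
  m <- as.matrix(table[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(table$sample_id)
  m
}

conc_tibble <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = NA) |>
    tibble::rownames_to_column("sample_id") |>
    tibble::as_tibble()
}
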