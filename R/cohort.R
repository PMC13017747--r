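# Core data containers: cohort feature tables and domain maps.

#' Construct a cohort table
#'
#' A `cohort_table` is the universal currency of the pipeline: one row per
#' individual, a unique identifier, numeric risk-factor columns (missing
#' values allowed), and a binary death outcome (1 = died within the
#' prediction window, 0 = survived; no missing values). Age (years) and
#' gender (1 = female, 0 = male) are ordinary features that are additionally
#' flagged so the demographic benchmark model and age-stratified summaries
#' can find them.
#'
#' @param data data.frame holding all columns.
#' @param id_col name of the unique-identifier column.
#' @param outcome_col name of the binary outcome column.
#' @param age_col name of the age column (years, in \[50, 110\]).
#' @param gender_col name of the gender column (1 = female, 0 = male).
#' @param feature_cols character vector of risk-factor columns (must include
#'   `age_col` and `gender_col`).
#' @return An object of class `cohort_table`: the data.frame with metadata
#'   attributes `id_col`, `outcome_col`, `age_col`, `gender_col`,
#'   `feature_cols`.
#' @export
cohort_table <- function(data, id_col = "id", outcome_col = "death",
                         age_col = "age", gender_col = "female",
                         feature_cols = setdiff(names(data),
                                                c(id_col, outcome_col))) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  declared <- c(id = id_col, outcome = outcome_col, age = age_col,
                gender = gender_col)
  missing_cols <- declared[!declared %in% names(data)]
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: declared column(s) not found: ",
         paste(sprintf("%s ('%s')", names(missing_cols), missing_cols),
               collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(feature_cols, names(data))
  if (length(absent) > 0L) {
    stop("cohort schema error: feature column(s) not found: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!all(c(age_col, gender_col) %in% feature_cols)) {
    stop("age_col and gender_col must be included in feature_cols",
         call. = FALSE)
  }
  if (anyDuplicated(names(data))) {
    stop("cohort validation error: duplicated column names", call. = FALSE)
  }
  if (anyDuplicated(data[[id_col]])) {
    stop("cohort validation error: ids are not unique", call. = FALSE)
  }
  y <- data[[outcome_col]]
  if (anyNA(y)) {
    stop("cohort validation error: missing outcome for id(s) ",
         paste(utils::head(data[[id_col]][is.na(y)], 5L), collapse = ", "),
         call. = FALSE)
  }
  bad <- !(y %in% c(0, 1))
  if (any(bad)) {
    stop("cohort validation error: non-binary outcome value ",
         y[bad][1L], " for id ", data[[id_col]][bad][1L], call. = FALSE)
  }
  age <- data[[age_col]]
  if (any(!is.na(age) & (age < 50 | age > 110))) {
    stop("cohort validation error: age outside [50, 110]", call. = FALSE)
  }
  g <- data[[gender_col]]
  if (any(!is.na(g) & !(g %in% c(0, 1)))) {
    stop("cohort validation error: gender must be coded 0/1 (1 = female)",
         call. = FALSE)
  }
  for (fc in feature_cols) {
    if (!is.numeric(data[[fc]])) {
      stop("cohort validation error: feature column '", fc,
           "' is not numeric", call. = FALSE)
    }
  }
  structure(data,
            id_col = id_col, outcome_col = outcome_col,
            age_col = age_col, gender_col = gender_col,
            feature_cols = feature_cols,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d individuals, %d risk factors, prevalence %.3f\n",
              nrow(x), length(feature_names(x)), mean(outcomes(x))))
  invisible(x)
}

#' Accessors for cohort tables
#'
#' @param table a `cohort_table`.
#' @return `feature_names()` the risk-factor column names; `outcomes()` the
#'   binary outcome vector; `cohort_ids()` the identifier vector;
#'   `feature_matrix()` the numeric risk-factor matrix (columns optionally
#'   restricted to `cols`).
#' @name cohort-accessors
#' @export
feature_names <- function(table) attr(table, "feature_cols")

#' @rdname cohort-accessors
#' @export
outcomes <- function(table) table[[attr(table, "outcome_col")]]

#' @rdname cohort-accessors
#' @export
cohort_ids <- function(table) table[[attr(table, "id_col")]]

#' @rdname cohort-accessors
#' @param cols optional subset of feature columns.
#' @export
feature_matrix <- function(table, cols = feature_names(table)) {
  absent <- setdiff(cols, names(table))
  if (length(absent) > 0L) {
    stop("feature column(s) not present: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

subset_rows <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  cohort_table(out,
               id_col = attr(table, "id_col"),
               outcome_col = attr(table, "outcome_col"),
               age_col = attr(table, "age_col"),
               gender_col = attr(table, "gender_col"),
               feature_cols = attr(table, "feature_cols"))
}

#' Construct a domain map
#'
#' Partitions the risk-factor columns of a cohort into named domains (the
#' unit of the coalition analysis). Up to 7 canonical domains are used in
#' the mortality application: demography, socioeconomic, psychology,
#' social_connections, childhood_adversity, adulthood_adversity,
#' health_behaviors, but any names are accepted.
#'
#' @param assignment named character vector: names are feature columns,
#'   values are domain names.
#' @param domains optional ordered vector of domain names; defaults to the
#'   order of first appearance in `assignment`.
#' @return An object of class `domain_map` with elements `assignment` and
#'   `domains`.
#' @export
domain_map <- function(assignment, domains = unique(unname(assignment))) {
  stopifnot(is.character(assignment), !is.null(names(assignment)))
  if (anyDuplicated(names(assignment))) {
    stop("domain map error: feature assigned more than once: ",
         paste(unique(names(assignment)[duplicated(names(assignment))]),
               collapse = ", "), call. = FALSE)
  }
  if (!setequal(domains, unique(unname(assignment)))) {
    stop("domain map error: `domains` must list exactly the assigned domains",
         call. = FALSE)
  }
  structure(list(assignment = assignment, domains = domains),
            class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  sizes <- table(factor(x$assignment, levels = x$domains))
  cat("<domain_map>", length(x$assignment), "features in",
      length(x$domains), "domains:\n")
  for (d in x$domains) cat(sprintf("  %-20s %d\n", d, sizes[[d]]))
  invisible(x)
}

#' Features belonging to a set of domains
#'
#' @param map a `domain_map`.
#' @param domains character vector of domain names.
#' @return Character vector of the feature columns assigned to those domains,
#'   in assignment order.
#' @export
domain_features <- function(map, domains) {
  unknown <- setdiff(domains, map$domains)
  if (length(unknown) > 0L) {
    stop("unknown domain(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  names(map$assignment)[map$assignment %in% domains]
}

validate_domain_map <- function(table, map) {
  feats <- feature_names(table)
  unmapped <- setdiff(feats, names(map$assignment))
  if (length(unmapped) > 0L) {
    stop("domain map validation error: feature(s) missing from domain map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(map$assignment), feats)
  if (length(extra) > 0L) {
    stop("domain map validation error: mapped feature(s) absent from cohort: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(map$domains, unique(unname(map$assignment)))
  if (length(empty) > 0L) {
    stop("domain map validation error: empty domain(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a cohort CSV and its domain-map configuration
#'
#' The CSV must have a header row, '.' decimal separator, and empty cells for
#' missing feature values. The configuration (YAML or JSON, by extension)
#' declares `outcome_col`, `id_col`, `age_col`, `gender_col` and a `domains`
#' mapping `domain name -> [feature columns]`.
#'
#' @param path CSV file path.
#' @param domain_map_path YAML/JSON configuration path.
#' @return list with elements `table` (a [cohort_table]) and `map`
#'   (a [domain_map]).
#' @export
load_cohort <- function(path, domain_map_path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  cfg <- read_config(domain_map_path)
  for (key in c("outcome_col", "id_col", "age_col", "gender_col", "domains")) {
    if (is.null(cfg[[key]])) {
      stop("domain map config missing key: ", key, call. = FALSE)
    }
  }
  raw <- utils::read.csv(path, check.names = FALSE, na.strings = "")
  assignment <- unlist(lapply(names(cfg$domains), function(d) {
    stats::setNames(rep(d, length(cfg$domains[[d]])),
                    unlist(cfg$domains[[d]]))
  }))
  map <- domain_map(assignment, domains = names(cfg$domains))
  # every risk-factor column in the file must be covered by the map
  # (columns listed under ignore_cols, e.g. a source label, are exempt)
  unmapped <- setdiff(names(raw),
                      c(cfg$id_col, cfg$outcome_col, names(assignment),
                        unlist(cfg$ignore_cols)))
  if (length(unmapped) > 0L) {
    stop("domain map validation error: feature(s) in the cohort file are ",
         "absent from the domain map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  table <- cohort_table(raw,
                        id_col = cfg$id_col, outcome_col = cfg$outcome_col,
                        age_col = cfg$age_col, gender_col = cfg$gender_col,
                        feature_cols = names(assignment))
  validate_domain_map(table, map)
  list(table = table, map = map)
}

#' Write a cohort to CSV (and optionally its domain map to YAML)
#'
#' Missing feature values become empty cells, so a write/load round trip
#' preserves numeric content and missingness.
#'
#' @param table a `cohort_table`.
#' @param path output CSV path.
#' @param map optional `domain_map`; when given, a full configuration is
#'   written to `map_path`.
#' @param map_path output path for the configuration (default: `path` with a
#'   `.yaml` extension).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path, map = NULL,
                         map_path = sub("\\.csv$", ".yaml", path)) {
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(map)) {
    cfg <- list(outcome_col = attr(table, "outcome_col"),
                id_col = attr(table, "id_col"),
                age_col = attr(table, "age_col"),
                gender_col = attr(table, "gender_col"),
                domains = lapply(stats::setNames(map$domains, map$domains),
                                 function(d) as.list(domain_features(map, d))))
    yaml::write_yaml(cfg, map_path)
  }
  invisible(path)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Split specification
#'
#' @param train_fraction proportion of rows assigned to the training set,
#'   in (0, 1). The conventional split for this analysis is 7:3.
#' @param seed integer seed controlling the partition.
#' @param stratified stratify the split by outcome (default TRUE), so train
#'   and test prevalences match closely; recommended for imbalanced
#'   outcomes evaluated with PR-AUC.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, seed = 1L, stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

#' Split a cohort into train and test sets
#'
#' Deterministic given the spec's seed; the train set holds
#' `round(train_fraction * n)` rows exactly. With stratification the
#' per-class counts are rounded so train/test prevalences agree as closely
#' as the integer counts allow.
#'
#' @param table a `cohort_table` with at least 10 rows and both classes.
#' @param spec a [split_spec].
#' @return list with `cohort_table` elements `train` and `test`.
#' @export
split_cohort <- function(table, spec = split_spec()) {
  n <- nrow(table)
  if (n < 10L) stop("cohort too small to split (need >= 10 rows)", call. = FALSE)
  y <- outcomes(table)
  n_train <- round(spec$train_fraction * n)
  idx_train <- with_seed(spec$seed, {
    if (spec$stratified) {
      if (length(unique(y)) < 2L) {
        stop("stratified split requires both outcome classes", call. = FALSE)
      }
      pos <- which(y == 1); neg <- which(y == 0)
      n_pos_train <- round(spec$train_fraction * length(pos))
      n_neg_train <- n_train - n_pos_train
      c(sample(pos, n_pos_train), sample(neg, n_neg_train))
    } else {
      sample.int(n, n_train)
    }
  })
  idx_train <- sort(idx_train)
  list(train = subset_rows(table, idx_train),
       test = subset_rows(table, setdiff(seq_len(n), idx_train)))
}

#' Concatenate cohorts row-wise on their shared risk factors
#'
#' Emulates pooled multi-survey analyses: cohorts harmonized to different
#' item sets are combined on the intersection of their feature columns, and
#' a `source` label column records provenance.
#'
#' @param tables named (or unnamed) list of `cohort_table`s.
#' @param shared_only restrict to the intersection of feature columns
#'   (default TRUE). The intersection must be non-empty.
#' @return A `cohort_table` with a `source` column appended (not a feature).
#' @export
concat_cohorts <- function(tables, shared_only = TRUE) {
  stopifnot(length(tables) >= 1L)
  labels <- names(tables)
  if (is.null(labels) || any(labels == "")) {
    labels <- paste0("cohort", seq_along(tables))
  }
  first <- tables[[1L]]
  shared <- Reduce(intersect, lapply(tables, feature_names))
  if (shared_only && length(shared) == 0L) {
    stop("concat error: cohorts share no feature columns", call. = FALSE)
  }
  keep <- if (shared_only) shared else feature_names(first)
  age_col <- attr(first, "age_col"); gender_col <- attr(first, "gender_col")
  if (!all(c(age_col, gender_col) %in% keep)) {
    stop("concat error: shared columns must include age and gender",
         call. = FALSE)
  }
  parts <- Map(function(tb, lab) {
    df <- as.data.frame(tb)[, c(attr(tb, "id_col"), attr(tb, "outcome_col"),
                                keep), drop = FALSE]
    names(df)[1:2] <- c(attr(first, "id_col"), attr(first, "outcome_col"))
    df[[attr(first, "id_col")]] <- paste(lab, df[[attr(first, "id_col")]],
                                         sep = ":")
    df$source <- lab
    df
  }, tables, labels)
  combined <- do.call(rbind, parts)
  rownames(combined) <- NULL
  out <- cohort_table(combined,
                      id_col = attr(first, "id_col"),
                      outcome_col = attr(first, "outcome_col"),
                      age_col = age_col, gender_col = gender_col,
                      feature_cols = keep)
  out
}
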