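## File I/O: phenotype CSV, expression TSV with design sidecar, ground-truth
## labels, and a GEO series-matrix reader.

PHENO_COLUMNS <- c("mouse_id", "arm", "sex", "litter_size", "age_days",
                   "bw_g", "fm_g", "lm_g", "leptin_ngml", "insulin_au",
                   "leptin_mrna_au", "adipocyte_area_au")

#' Write / read a phenotype table as CSV
#'
#' The documented header is `mouse_id, arm, sex, litter_size, age_days,
#' bw_g, fm_g, lm_g, leptin_ngml, insulin_au, leptin_mrna_au,
#' adipocyte_area_au`; internal latent columns of the generator are not
#' written.
#'
#' @param phen Phenotype data frame (class `ate_phenotypes`).
#' @param path Output CSV path.
#' @return `write_phenotypes()` the path invisibly; `read_phenotypes()` an
#'   `ate_phenotypes` data frame.
#' @export
write_phenotypes <- function(phen, path) {
  missing <- setdiff(PHENO_COLUMNS, names(phen))
  if (length(missing))
    stop("phenotype table lacks column(s): ",
         paste(missing, collapse = ", "))
  utils::write.csv(phen[, PHENO_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  phen <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PHENO_COLUMNS, names(phen))
  if (length(missing))
    stop("malformed phenotype CSV, missing column(s): ",
         paste(missing, collapse = ", "))
  class(phen) <- c("ate_phenotypes", "data.frame")
  phen
}

#' Write / read an expression matrix as TSV with a design sidecar
#'
#' The TSV holds `gene_id` as first column and one column per array; the
#' sidecar CSV (same path with `_design.csv` appended before the
#' extension is replaced) maps `array_id` to `(arm, age_days,
#' replicate_index)`. Round-trips are lossless for ids and full-precision
#' signals.
#'
#' @param expr An [ate_expression()] object.
#' @param path Output TSV path; the design sidecar path defaults to
#'   `sub("\\\\.tsv$", "_design.csv", path)`.
#' @param design_path Optional explicit sidecar path.
#' @return `write_expression()` the path invisibly; `read_expression()` an
#'   `ate_expression` object.
#' @export
write_expression <- function(expr, path, design_path = NULL) {
  stopifnot(inherits(expr, "ate_expression"))
  if (is.null(design_path)) design_path <- design_sidecar_path(path)
  df <- data.frame(gene_id = rownames(expr$values),
                   expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  sc <- data.frame(array_id = expr$design$array_id,
                   arm = expr$design$arm,
                   age_days = expr$design$age_days,
                   replicate_index = expr$design$replicate)
  utils::write.csv(sc, design_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

design_sidecar_path <- function(path) {
  sub("\\.tsv$", "_design.csv", path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, design_path = NULL) {
  if (is.null(design_path)) design_path <- design_sidecar_path(path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop("malformed expression TSV: first column must be 'gene_id', got '",
         names(df)[1], "'")
  dups <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dups))
    stop("duplicated gene ids: ", paste(utils::head(dups, 10),
                                        collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  sc <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  need <- c("array_id", "arm", "age_days", "replicate_index")
  if (!all(need %in% names(sc)))
    stop("malformed design sidecar, missing column(s): ",
         paste(setdiff(need, names(sc)), collapse = ", "))
  design <- data.frame(array_id = sc$array_id, arm = sc$arm,
                       age_days = as.integer(sc$age_days),
                       replicate = as.integer(sc$replicate_index),
                       cell = cell_key(sc$arm, sc$age_days),
                       stringsAsFactors = FALSE)
  class(design) <- c("ate_design", "data.frame")
  ate_expression(m, design)
}

#' Write ground-truth gene class labels as TSV
#'
#' @param truth Data frame with `gene_id` and `gene_class` (as in the
#'   `truth` element of [generate_expression()]).
#' @param path Output TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth[, c("gene_id", "gene_class")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the tab-delimited series-matrix format (`!`-prefixed metadata
#' lines, expression block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`). Sample titles are mapped to (arm, age,
#' replicate) through a configurable regular expression, since deposited
#' title conventions vary; samples whose titles do not match are reported
#' in the `unparsed` attribute rather than guessed.
#'
#' @param path Local series-matrix file (uncompressed text).
#' @param title_regex Regex with three capture groups: arm label, age in
#'   days, replicate index.
#' @param arm_map Named character vector translating captured arm labels to
#'   `CONTROL`/`LUN`/`LON`.
#' @return An [ate_expression()] object restricted to parseable samples,
#'   with attribute `unparsed` listing dropped sample titles.
#' @export
read_geo_series_matrix <- function(path,
                                   title_regex =
                                     "^([A-Za-z]+)[ _-]?d(?:ay)?[ _-]?([0-9]+)[ _-]?(?:rep|r)?[ _-]?([0-9]+)$",
                                   arm_map = c(control = "CONTROL",
                                               c = "CONTROL",
                                               con = "CONTROL",
                                               lun = "LUN", u = "LUN",
                                               lon = "LON", o = "LON")) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
    stop("missing expression block (!series_matrix_table_begin/end) in ",
         path)
  meta <- lines[seq_len(begin - 1)]
  titles_line <- grep("^!Sample_title", meta, value = TRUE)
  if (length(titles_line) != 1)
    stop("missing !Sample_title metadata line in ", path)
  titles <- gsub('^"|"$', "",
                 strsplit(titles_line, "\t")[[1]][-1])

  tab <- utils::read.delim(text = lines[(begin + 1):(end - 1)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (length(titles) != ncol(m))
    stop("sample title count (", length(titles),
         ") does not match expression columns (", ncol(m), ")")

  mm <- regmatches(titles, regexec(title_regex, titles,
                                   ignore.case = TRUE))
  parsed <- lengths(mm) == 4
  arm_raw <- tolower(vapply(mm[parsed], `[`, "", 2))
  arm <- unname(arm_map[arm_raw])
  age <- as.integer(vapply(mm[parsed], `[`, "", 3))
  rep_i <- as.integer(vapply(mm[parsed], `[`, "", 4))
  bad_arm <- is.na(arm) | !(age %in% AGES)
  keep <- which(parsed)[!bad_arm]
  unparsed <- titles[setdiff(seq_along(titles), keep)]
  if (length(unparsed))
    warning(length(unparsed), " sample(s) with unparseable titles dropped: ",
            paste(utils::head(unparsed, 5), collapse = ", "))
  if (!length(keep)) stop("no parseable samples in ", path)
  arm <- arm[!bad_arm]; age <- age[!bad_arm]; rep_i <- rep_i[!bad_arm]
  design <- data.frame(array_id = colnames(m)[keep], arm = arm,
                       age_days = age, replicate = rep_i,
                       cell = cell_key(arm, age),
                       stringsAsFactors = FALSE)
  class(design) <- c("ate_design", "data.frame")
  out <- ate_expression(m[, keep, drop = FALSE], design)
  attr(out, "unparsed") <- unparsed
  out
}
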