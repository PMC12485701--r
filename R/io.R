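# Reading/writing expression matrices and sample sheets.
#
# The in-memory container is a SummarizedExperiment with a single "tpm" assay,
# rowData columns gene_id / symbol / chromosome, and (after alignSamples) the
# sample sheet in colData.  Matrices are genes-in-rows in every dialect;
# transposed inputs must be declared explicitly, never guessed.

.validateExpressionValues <- function(values, what = "expression matrix") {
  if (!is.numeric(values))
    stop("validation error: non-numeric values in ", what, call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("validation error: missing or non-finite values in ", what,
         " (missing entries are rejected, not imputed)", call. = FALSE)
  if (any(values < 0))
    stop("validation error: negative expression values in ", what, call. = FALSE)
  invisible(TRUE)
}

.makeSE <- function(values, gene_id, symbol = gene_id, chromosome = NULL) {
  gene_id <- stripGeneVersion(as.character(gene_id))
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("collision error: duplicate gene ids after version-suffix stripping: ",
         paste(utils::head(dup, 10L), collapse = ", "),
         if (length(dup) > 10L) ", ..." else "", call. = FALSE)
  }
  if (anyDuplicated(colnames(values)))
    stop("validation error: duplicate sample ids in expression matrix",
         call. = FALSE)
  .validateExpressionValues(values)
  storage.mode(values) <- "double"
  if (is.null(chromosome)) chromosome <- rep("other", length(gene_id))
  rd <- DataFrame(gene_id = gene_id,
                  symbol = as.character(symbol),
                  chromosome = normalizeChromosome(chromosome),
                  row.names = gene_id)
  rownames(values) <- gene_id
  SummarizedExperiment(assays = list(tpm = values), rowData = rd)
}

#' Read a gene-level TPM expression matrix
#'
#' Supports GCT v1.2 (`#1.2` header line, dimensions line, `Name` /
#' `Description` columns) and plain delimited genes-by-samples tables.  For
#' `tsv`/`csv` dialects the first column holds gene ids; optional columns
#' named `symbol` and `chromosome` (any case) are consumed as gene annotation
#' and all remaining columns are treated as samples.  Ensembl-style version
#' suffixes are stripped from gene ids and chromosome labels are normalized
#' via [normalizeChromosome()].
#'
#' @param path path to the file.
#' @param dialect one of `"gct"`, `"tsv"`, `"csv"`.  Defaults to a guess from
#'   the file extension (`.gct` -> gct, `.csv` -> csv, otherwise tsv).
#' @param transposed set `TRUE` if the file is samples-in-rows; the matrix is
#'   then transposed after reading.  Orientation is never auto-detected.
#' @param chromosomes optional named character vector mapping gene id or
#'   symbol to a chromosome label, applied after reading.
#' @return [SummarizedExperiment::SummarizedExperiment] with assay `tpm`.
#' @export
readExpression <- function(path, dialect = NULL, transposed = FALSE,
                           chromosomes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, gct = "gct", csv = "csv", "tsv")
  }
  dialect <- match.arg(dialect, c("gct", "tsv", "csv"))
  se <- if (dialect == "gct") .readGCT(path) else
    .readDelimMatrix(path, sep = if (dialect == "csv") "," else "\t",
                     transposed = transposed)
  if (!is.null(chromosomes)) se <- setChromosomes(se, chromosomes)
  se
}

.readGCT <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || !startsWith(header[[1L]], "#1.2"))
    stop("format error: not a GCT v1.2 file (missing '#1.2' header): ", path,
         call. = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(header[[2L]], "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("format error: malformed GCT dimensions line", call. = FALSE)
  tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || !identical(tolower(names(tab)[1:2]), c("name", "description")))
    stop("format error: GCT data header must start with Name, Description",
         call. = FALSE)
  if (nrow(tab) != dims[[1L]] || ncol(tab) - 2L != dims[[2L]])
    stop("format error: GCT declared dimensions (", dims[[1L]], " x ",
         dims[[2L]], ") do not match data (", nrow(tab), " x ",
         ncol(tab) - 2L, ")", call. = FALSE)
  values <- as.matrix(tab[, -(1:2), drop = FALSE])
  .makeSE(values, gene_id = tab[[1L]], symbol = tab[[2L]])
}

.readDelimMatrix <- function(path, sep, transposed = FALSE) {
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("format error: expected an id column plus at least one sample column",
         call. = FALSE)
  if (transposed) {
    ids <- as.character(tab[[1L]])
    values <- t(as.matrix(tab[, -1L, drop = FALSE]))
    colnames(values) <- ids
    return(.makeSE(values, gene_id = rownames(values)))
  }
  lower <- tolower(names(tab))
  symcol <- match("symbol", lower)
  chrcol <- match("chromosome", lower)
  meta <- c(1L, symcol, chrcol)
  meta <- meta[!is.na(meta)]
  values <- as.matrix(tab[, -meta, drop = FALSE])
  .makeSE(values,
          gene_id = tab[[1L]],
          symbol = if (!is.na(symcol)) tab[[symcol]] else tab[[1L]],
          chromosome = if (!is.na(chrcol)) tab[[chrcol]] else NULL)
}

#' Attach chromosome labels to an expression object
#'
#' @param se SummarizedExperiment from [readExpression()].
#' @param map named character vector: names are gene ids or symbols, values
#'   chromosome labels (normalized on assignment).  Genes absent from the map
#'   keep their current label.
#' @return the updated SummarizedExperiment.
#' @export
setChromosomes <- function(se, map) {
  rd <- rowData(se)
  hit <- match(rd$gene_id, names(map))
  miss <- is.na(hit)
  hit[miss] <- match(rd$symbol[miss], names(map))
  upd <- !is.na(hit)
  rd$chromosome[upd] <- normalizeChromosome(unname(map[hit[upd]]))
  rowData(se) <- rd
  se
}

#' Write an expression matrix
#'
#' `tsv` writes a full-precision genes-by-samples table with `gene_id`,
#' `symbol` and `chromosome` annotation columns (round-trips exactly through
#' [readExpression()]); `gct` writes GCT v1.2 (chromosome labels are not part
#' of that format and are dropped).
#'
#' @param se SummarizedExperiment with a `tpm` assay.
#' @param path output path.
#' @param dialect `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(se, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  values <- assay(se, "tpm")
  rd <- rowData(se)
  fmt <- function(m) apply(m, 2L, function(col) sprintf("%.17g", col))
  if (dialect == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(se), ncol(se), sep = "\t")), con)
    tab <- cbind(Name = rd$gene_id, Description = rd$symbol, fmt(values))
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- cbind(gene_id = rd$gene_id, symbol = rd$symbol,
                 chromosome = rd$chromosome, fmt(values))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.SEX_LEVELS <- c("female", "male", "unknown")
.TYPE_LEVELS <- c("normal", "adjacent_normal", "primary_tumor", "cell_line")

#' Read a sample sheet
#'
#' Delimited file with required columns `sample_id`, `tissue`, `reported_sex`
#' and optional columns `subject_id`, `age_years`, `sample_type`, `x_ploidy`,
#' `survival_days`, `event`.  Sex strings are case-normalized; anything not
#' female/male becomes `"unknown"`.  `event` accepts death/dead/deceased/1 and
#' censored/alive/0.  Missing optional fields become `NA` (`x_ploidy`:
#' "unknown").
#'
#' @param path path to a TSV or CSV sample sheet (delimiter from extension).
#' @return [S4Vectors::DataFrame] with one row per sample, row names =
#'   sample ids.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  names(tab) <- tolower(names(tab))
  req <- c("sample_id", "tissue", "reported_sex")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("schema error: sample sheet lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$sample_id))
    stop("validation error: duplicate sample_id in sample sheet: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "),
         call. = FALSE)
  n <- nrow(tab)
  opt <- function(col, default = NA_character_)
    if (col %in% names(tab)) tab[[col]] else rep(default, n)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c("", "NA"), NA, x)))

  sex <- tolower(trimws(opt("reported_sex")))
  sex[!(sex %in% c("female", "male"))] <- "unknown"

  type <- tolower(trimws(opt("sample_type")))
  type[!(type %in% .TYPE_LEVELS)] <- NA_character_

  ploidy <- trimws(opt("x_ploidy"))
  ploidy[!(ploidy %in% c("1", "2"))] <- "unknown"

  event_raw <- tolower(trimws(opt("event")))
  event <- rep(NA_integer_, n)
  event[event_raw %in% c("death", "dead", "deceased", "1")] <- 1L
  event[event_raw %in% c("censored", "alive", "0")] <- 0L

  age <- num(opt("age_years"))
  if (any(age < 0, na.rm = TRUE))
    stop("validation error: negative age_years", call. = FALSE)
  surv <- num(opt("survival_days"))
  if (any(surv < 0, na.rm = TRUE))
    stop("validation error: negative survival_days", call. = FALSE)
  if (any(!is.na(event) & is.na(surv)))
    stop("validation error: event recorded without survival_days for sample(s): ",
         paste(tab$sample_id[!is.na(event) & is.na(surv)], collapse = ", "),
         call. = FALSE)

  DataFrame(sample_id = tab$sample_id,
            subject_id = ifelse(is.na(opt("subject_id")) | opt("subject_id") == "",
                                tab$sample_id, opt("subject_id")),
            tissue = tab$tissue,
            reported_sex = sex,
            age_years = age,
            sample_type = type,
            x_ploidy = ploidy,
            survival_days = surv,
            event = event,
            row.names = tab$sample_id)
}

#' Align an expression matrix with a sample sheet
#'
#' Restricts both to the intersection of sample ids (in the matrix's column
#' order), reports how many samples were dropped from each side, and returns
#' the matrix with the sample sheet installed as `colData`.  Idempotent.
#'
#' @param se SummarizedExperiment with a `tpm` assay.
#' @param annotations DataFrame/data.frame from [readSampleSheet()] (or the
#'   colData of a previous alignment).
#' @return SummarizedExperiment restricted to shared samples with annotations
#'   in `colData`.
#' @export
alignSamples <- function(se, annotations) {
  annotations <- as(annotations, "DataFrame")
  ids <- intersect(colnames(se), annotations$sample_id)
  if (!length(ids))
    stop("alignment error: no shared sample ids between matrix and sample sheet",
         call. = FALSE)
  dropped_m <- ncol(se) - length(ids)
  dropped_a <- nrow(annotations) - length(ids)
  if (dropped_m || dropped_a)
    message("alignSamples: dropped ", dropped_m, " matrix sample(s) and ",
            dropped_a, " annotation row(s) without a match")
  keep <- colnames(se)[colnames(se) %in% ids]
  out <- se[, keep]
  colData(out) <- annotations[match(keep, annotations$sample_id), , drop = FALSE]
  out
}
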