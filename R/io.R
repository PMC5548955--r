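# Readers and writers for the plain-text formats the pipeline exchanges:
# gene-level count matrices (TSV), sample sheets (TSV), gene sets (GMT),
# gene-to-clan maps (two-column TSV), gene effective lengths (two-column
# TSV) and results tables (TSV).  All readers validate strictly and name
# the offending gene/sample/line on failure.

.FRACTIONS <- c("IP", "Input")
.GENOTYPES <- c("WT", "KO")

#' Validate a count matrix
#'
#' Checks the invariants every count matrix entering the pipeline must
#' satisfy: a numeric matrix of non-negative integers with unique,
#' non-missing gene (row) and sample (column) identifiers.
#'
#' @param counts matrix of gene-level counts, genes in rows, samples in
#'   columns, with `rownames` and `colnames` set.
#' @return `counts`, invisibly, with storage mode coerced to integer-valued
#'   numeric.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_fmt("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("counts must have gene (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop_fmt("duplicate gene id: %s",
             rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop_fmt("duplicate sample id: %s",
             colnames(counts)[duplicated(colnames(counts))][1L])
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop_fmt("invalid count '%s' for gene '%s', sample '%s' (non-negative integers required)",
             format(counts[bad[1L]]), rownames(counts)[i[1L]],
             colnames(counts)[i[2L]])
  }
  invisible(counts)
}

#' Read a gene-level count matrix
#'
#' Reads a TSV with a header row of sample identifiers and gene identifiers
#' in the first column.  When a sample sheet is supplied the columns are
#' reordered to the sheet's sample order and every sheet sample must be
#' present in the file.
#'
#' @param path path to the counts TSV.
#' @param sample_sheet optional sample sheet (see [read_sample_sheet()])
#'   used to order and cross-check the columns.
#' @return An integer matrix, genes x samples.
#' @export
read_counts <- function(path, sample_sheet = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2L) stop_fmt("counts file '%s' has no sample columns", path)
  genes <- tab[[1L]]
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(genes, colnames(mat))))
  bad <- which(is.na(num) | num < 0 | num != floor(num))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(num))
    stop_fmt("invalid count '%s' for gene '%s', sample '%s' in '%s'",
             mat[bad[1L]], genes[i[1L]], colnames(num)[i[2L]], path)
  }
  validate_counts(num)
  if (!is.null(sample_sheet)) {
    missing <- setdiff(sample_sheet$sample_id, colnames(num))
    if (length(missing))
      stop_fmt("sample '%s' in sample sheet but not in counts file",
               missing[1L])
    num <- num[, sample_sheet$sample_id, drop = FALSE]
  }
  num
}

#' Write a count matrix
#'
#' @param counts validated count matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sheet is a TSV with columns `sample_id`, `fraction`, `genotype`,
#' `pair_id` and `animal_id`.  Fraction and genotype tokens are parsed
#' case-insensitively and normalized to `IP`/`Input` and `WT`/`KO`.  Each
#' (pair, genotype) may contribute at most one IP and one Input sample.
#'
#' @param path path to the TSV sheet.
#' @return A `data.frame` with normalized factor columns.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character", quote = "")
  validate_sample_sheet(tab)
}

#' @rdname read_sample_sheet
#' @param sheet a data.frame with the sample-sheet columns, validated and
#'   normalized in place.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "fraction", "genotype", "pair_id")
  missing <- setdiff(required, names(sheet))
  if (length(missing))
    stop_fmt("sample sheet lacks column(s): %s",
             paste(missing, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop_fmt("duplicate sample_id '%s' in sample sheet",
             sheet$sample_id[duplicated(sheet$sample_id)][1L])
  norm_token <- function(x, allowed, what) {
    idx <- match(tolower(x), tolower(allowed))
    if (anyNA(idx)) {
      bad <- x[is.na(idx)][1L]
      stop_fmt("unknown %s token '%s' (allowed: %s)", what, bad,
               paste(allowed, collapse = ", "))
    }
    allowed[idx]
  }
  sheet$fraction <- norm_token(sheet$fraction, .FRACTIONS, "fraction")
  sheet$genotype <- norm_token(sheet$genotype, .GENOTYPES, "genotype")
  pair <- suppressWarnings(as.integer(sheet$pair_id))
  if (anyNA(pair))
    stop_fmt("non-integer pair_id '%s' in sample sheet",
             sheet$pair_id[is.na(pair)][1L])
  sheet$pair_id <- pair
  if (is.null(sheet$animal_id))
    sheet$animal_id <- paste(sheet$pair_id, sheet$genotype, sep = "_")
  key <- paste(sheet$pair_id, sheet$genotype, sheet$fraction)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_fmt("more than one sample for pair/genotype/fraction '%s'", dup)
  }
  sheet
}

#' Write a sample sheet
#' @param sheet validated sample sheet.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  cols <- c("sample_id", "fraction", "genotype", "pair_id", "animal_id")
  utils::write.table(sheet[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per tab-separated line: name, description, then gene ids.
#' Duplicate genes within a line are removed with a warning.
#'
#' @param path path to the GMT file.
#' @return A named list of gene sets; each element is a list with `name`,
#'   `description` and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop_fmt("GMT line %d has %d field(s); need name, description, genes",
               i, length(fields))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn_fmt("gene set '%s': %d duplicate gene id(s) removed",
               fields[1L], sum(duplicated(genes)))
      genes <- unique(genes)
    }
    out[[fields[1L]]] <- list(name = fields[1L], description = fields[2L],
                              genes = genes)
  }
  out
}

#' Write gene sets in GMT format
#' @param sets named list of gene sets as returned by [read_gmt()], or a
#'   named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (is.character(s)) s <- list(name = nm, description = nm, genes = s)
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-to-clan map
#'
#' Two-column TSV of `gene_id`, `clan_id`; a gene may appear on several
#' rows (one per clan).  Genes absent from the file belong to no clan.
#'
#' @param path path to the TSV map.
#' @return A `data.frame` with columns `gene_id` and `clan_id`, one row per
#'   membership, duplicates removed.
#' @export
read_clan_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_id = character(), clan_id = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- identical(tolower(fields[[1L]][1:2]), c("gene_id", "clan_id"))
  start <- if (header) 2L else 1L
  if (start > length(lines))
    return(data.frame(gene_id = character(), clan_id = character(),
                      stringsAsFactors = FALSE))
  for (i in seq(start, length(fields))) {
    if (length(fields[[i]]) != 2L || !all(nzchar(fields[[i]])))
      stop_fmt("malformed clan map line %d: '%s'", i, lines[[i]])
  }
  map <- data.frame(
    gene_id = vapply(fields[start:length(fields)], `[[`, "", 1L),
    clan_id = vapply(fields[start:length(fields)], `[[`, "", 2L),
    stringsAsFactors = FALSE)
  unique(map)
}

#' Write a gene-to-clan map
#' @param map data.frame with `gene_id` and `clan_id` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clan_map <- function(map, path) {
  utils::write.table(map[, c("gene_id", "clan_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a long-format clan map to a list of clan gene sets
#' @param map data.frame from [read_clan_map()].
#' @return Named list: clan id -> character vector of gene ids.
#' @export
clan_sets <- function(map) {
  if (!nrow(map)) return(list())
  split(map$gene_id, map$clan_id)
}

#' Read gene effective lengths
#'
#' Two-column TSV of `gene_id`, `length` (bases).  Lengths must be strictly
#' positive.
#'
#' @param path path to the TSV file.
#' @return A named numeric vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric"),
                           comment.char = "#", quote = "")
  if (any(!is.finite(tab[[2L]]) | tab[[2L]] <= 0)) {
    bad <- tab[[1L]][which(!is.finite(tab[[2L]]) | tab[[2L]] <= 0)][1L]
    stop_fmt("non-positive length for gene '%s'", bad)
  }
  if (anyDuplicated(tab[[1L]]))
    stop_fmt("duplicate gene id '%s' in lengths file",
             tab[[1L]][duplicated(tab[[1L]])][1L])
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write gene effective lengths
#' @param lengths named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_lengths <- function(lengths, path) {
  utils::write.table(
    data.frame(gene_id = names(lengths), length = as.numeric(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table
#'
#' Writes a data.frame as TSV with a stable column order and `NA` for
#' missing values; used for DE tables, enrichment tables and reports.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param header optional character vector of `#`-prefixed comment lines
#'   (version, seed, configuration digest) written before the table.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
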