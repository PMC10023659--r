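#' Read a gene-by-sample count matrix
#'
#' Counts are read either from a TSV with genes in rows (first column = gene
#' identifier, header row = sample identifiers) or from a MatrixMarket triplet
#' file accompanied by `<stem>.genes.txt` and `<stem>.samples.txt` index files
#' (one identifier per line, matching the MTX row/column order).
#'
#' @param path Path to the counts file (`.tsv` or `.mtx`).
#' @param format Either `"tsv"` or `"mtx"`. Defaults to the file extension.
#' @return An integer matrix, genes x samples, with identifier dimnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(tab) == 0L || ncol(tab) < 2L) stop("empty or malformed counts TSV: ", path)
    genes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- genes
  } else {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    gfile <- paste0(stem, ".genes.txt")
    sfile <- paste0(stem, ".samples.txt")
    if (!file.exists(gfile) || !file.exists(sfile)) {
      stop("MTX index files missing: expected ", gfile, " and ", sfile)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gfile)
    colnames(m) <- readLines(sfile)
  }
  validate_counts(m)
}

#' Validate a count matrix
#'
#' Enforces the count-matrix contract: unique gene and sample identifiers,
#' non-negative integer entries, at least 2 genes and 2 samples.
#'
#' @param m A numeric matrix with dimnames.
#' @return The validated matrix, in integer storage mode.
#' @export
validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix must carry gene and sample identifiers as dimnames")
  }
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g)) stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s)) stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (nrow(m) < 2L || ncol(m) < 2L) stop("count matrix needs >= 2 genes and >= 2 samples")
  if (!is.numeric(m)) stop("count matrix must be numeric")
  if (anyNA(m)) stop("count matrix contains missing values")
  if (any(m < 0)) stop("count matrix contains negative entries")
  if (any(m != round(m))) stop("count matrix contains non-integer entries")
  storage.mode(m) <- "integer"
  m
}

.tox_levels <- c("neg", "atypical", "typical", "mixed", "none")
.diag_levels <- c("control", "case")

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `diagnosis` (control/case), `tox_group`
#' (neg/atypical/typical/mixed, or `none` for controls only), `sex`, `age`
#' (years), `rin`, `pmi` (hours), `ph`, `batch`, `effective_mapping_rate` and
#' `intergenic_rate` (fractions).
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` with validated columns; `diagnosis`, `tox_group`,
#'   `sex` and `batch` are factors.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(tab)
}

#' Validate a sample metadata table
#'
#' @param tab A data.frame as returned by [read_metadata()].
#' @return The validated data.frame.
#' @export
validate_metadata <- function(tab) {
  required <- c("sample_id", "diagnosis", "tox_group", "sex", "age", "rin",
                "pmi", "ph", "batch", "effective_mapping_rate", "intergenic_rate")
  missing <- setdiff(required, colnames(tab))
  if (length(missing)) stop("metadata missing required column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  bad_diag <- setdiff(unique(tab$diagnosis), .diag_levels)
  if (length(bad_diag)) stop("invalid diagnosis level(s): ", paste(bad_diag, collapse = ", "))
  bad_tox <- setdiff(unique(tab$tox_group), .tox_levels)
  if (length(bad_tox)) stop("invalid tox_group level(s): ", paste(bad_tox, collapse = ", "))
  none_on_case <- tab$tox_group == "none" & tab$diagnosis == "case"
  if (any(none_on_case)) {
    stop("tox_group 'none' is only permitted for controls; offending samples: ",
         paste(tab$sample_id[none_on_case], collapse = ", "))
  }
  if (any(!is.finite(tab$age)) || any(tab$age <= 0)) stop("age must be > 0 for all samples")
  if (any(!is.finite(tab$rin)) || any(tab$rin < 0 | tab$rin > 10)) {
    stop("rin out of range [0, 10]")
  }
  for (col in c("effective_mapping_rate", "intergenic_rate")) {
    if (any(!is.finite(tab[[col]])) || any(tab[[col]] < 0 | tab[[col]] > 1)) {
      stop(col, " out of range [0, 1]")
    }
  }
  tab$diagnosis <- factor(tab$diagnosis, levels = .diag_levels)
  tab$tox_group <- factor(tab$tox_group, levels = .tox_levels)
  tab$sex <- factor(tab$sex)
  tab$batch <- factor(tab$batch)
  tab
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member gene identifiers. Duplicate members within a set are dropped
#' (first occurrence kept).
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors, with a `description` attribute
#'   (named character vector) on the list.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  names_ <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields")
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set on GMT line ", i)
    names_[i] <- fields[[1L]]
    descs[i] <- fields[[2L]]
    sets[[i]] <- members[!duplicated(members)]
  }
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  names(sets) <- names_
  names(descs) <- names_
  attr(sets, "description") <- descs
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-to-one orthology map
#'
#' Two-column TSV (no header) of paired gene identifiers, dataset A then
#' dataset B. Any identifier occurring in more than one row violates
#' one-to-one-ness; all rows touching such an identifier are dropped and the
#' count of dropped rows is reported via a message.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `gene_a`, `gene_b`.
#' @export
read_orthology <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("gene_a", "gene_b"),
                           stringsAsFactors = FALSE)
  validate_orthology(tab)
}

#' Validate (and de-duplicate) an orthology map
#' @param tab A two-column data.frame (`gene_a`, `gene_b`).
#' @return The filtered data.frame with strictly one-to-one pairs.
#' @export
validate_orthology <- function(tab) {
  keep <- !(tab$gene_a %in% tab$gene_a[duplicated(tab$gene_a)]) &
    !(tab$gene_b %in% tab$gene_b[duplicated(tab$gene_b)])
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " orthology row(s) dropped for violating one-to-one mapping")
  }
  out <- tab[keep, , drop = FALSE]
  if (nrow(out) < 1L) stop("no valid one-to-one orthology pairs remain")
  rownames(out) <- NULL
  out
}

#' Write a numeric table as TSV
#'
#' All floating-point values are written with 6 significant digits so outputs
#' are diff-able across runs and platforms.
#'
#' @param x A matrix or data.frame. Matrices are written with a leading
#'   identifier column named by `id_col`.
#' @param path Output path.
#' @param id_col Name for the rowname column when `x` is a matrix.
#' @export
write_tsv <- function(x, path, id_col = "id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), signif(x, 6), check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c(id_col, colnames(x))
  } else {
    df <- as.data.frame(x)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by [write_tsv()] as a matrix
#' @param path Path to the TSV.
#' @param id_col Identifier column name.
#' @return A numeric matrix with rownames from `id_col`.
#' @export
read_tsv_matrix <- function(path, id_col = "id") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, setdiff(colnames(tab), id_col), drop = FALSE])
  rownames(m) <- tab[[id_col]]
  m
}

#' Build a run manifest
#'
#' Records the configuration snapshot, seed, input-file MD5 digests, and
#' per-stage dimensions so a run can be audited and reproduced.
#'
#' @param config The configuration list used for the run.
#' @param seed Integer seed.
#' @param inputs Character vector of input file paths to digest.
#' @param stages Named list of per-stage records (dimensions, counts).
#' @return A list serializable with [write_manifest()].
#' @export
build_manifest <- function(config, seed, inputs = character(), stages = list()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(
    package = "sigconfound",
    version = as.character(utils::packageVersion("sigconfound")),
    seed = seed,
    config = config,
    input_digests = digests,
    stages = stages
  )
}

#' Write a manifest as JSON
#' @param manifest List from [build_manifest()].
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
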