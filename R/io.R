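#' Read a FASTA file with key=value header metadata
#'
#' Headers follow the dialect written by [write_fasta()]: the first
#' whitespace-separated token is the record id, subsequent tokens of the form
#' `key=value` are parsed into columns (`class` and `topology` are the two the
#' pipeline uses; unknown keys are preserved). `T`/`t` bases are mapped to `U`
#' so DNA-alphabet input is accepted.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `seq`, `class`, `topology`, plus
#'   one column per additional header key.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_domain("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      class = character(), topology = character(),
                      stringsAsFactors = FALSE))
  }
  headers <- names(set)
  seqs <- toupper(chartr("Tt", "Uu", as.character(set)))
  ids <- sub("\\s.*$", "", headers)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop_domain("FASTA parse error: record ", which(!nzchar(ids))[1], " has an empty id")
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop_domain("FASTA parse error: record '", ids[which(bad)[1]],
                "' contains characters outside {A,C,G,U/T}")
  }
  meta_tokens <- lapply(strsplit(headers, "\\s+"), function(tok) tok[-1])
  keys <- unique(unlist(lapply(meta_tokens, function(tok) sub("=.*$", "", tok))))
  keys <- keys[nzchar(keys)]
  out <- data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
  for (k in keys) {
    out[[k]] <- vapply(meta_tokens, function(tok) {
      hit <- grep(paste0("^", k, "="), tok, value = TRUE)
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
    }, character(1))
  }
  if (is.null(out$class)) out$class <- NA_character_
  if (is.null(out$topology)) out$topology <- "linear"
  out$topology[is.na(out$topology)] <- "linear"
  out
}

#' Write sequences as FASTA with key=value headers
#'
#' @param ids,seqs Character vectors of equal length.
#' @param path Output path.
#' @param class RNA class written as `class=` on every header.
#' @param topology `"linear"` or `"circular"` (recycled).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, class = NA_character_,
                        topology = "linear") {
  stopifnot(length(ids) == length(seqs))
  topology <- rep_len(topology, length(ids))
  hdr <- ids
  if (!is.na(class)) hdr <- paste0(hdr, " class=", class)
  hdr <- paste0(hdr, " topology=", topology)
  lines <- character(0)
  if (length(ids)) {
    lines <- as.vector(rbind(paste0(">", hdr), seqs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample map (sample_id, group)
#'
#' @param path TSV with columns `sample_id` and `group`; groups must be
#'   `case`/`control`.
#' @return A `data.frame` with columns `sample_id`, `group`.
#' @export
read_sample_map <- function(path) {
  sm <- read_tsv_commented(path)
  if (!all(c("sample_id", "group") %in% names(sm))) {
    stop_domain("sample map must have columns sample_id and group")
  }
  sm$sample_id <- as.character(sm$sample_id)
  if (!all(sm$group %in% c("case", "control"))) {
    stop_domain("sample map groups must be 'case' or 'control'")
  }
  if (anyDuplicated(sm$sample_id)) stop_domain("duplicated sample ids in sample map")
  sm[c("sample_id", "group")]
}

#' Read a count matrix TSV into a CountMatrix
#'
#' First column is the feature id, remaining columns are sample ids. Cells
#' must be non-negative integers. If a sample map is supplied every matrix
#' column must appear in it.
#'
#' @param path Count TSV path.
#' @param sample_map Optional `data.frame` from [read_sample_map()] (or a path).
#' @param class RNA class label for the matrix.
#' @return A [count_matrix()] object.
#' @export
read_counts <- function(path, sample_map = NULL, class = "mRNA") {
  df <- read_tsv_commented(path)
  if (ncol(df) < 1L) stop_domain("count matrix parse error: no columns in ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop_domain("count matrix parse error: duplicated feature id '",
                ids[duplicated(ids)][1], "'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) > 0) {
    if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
      stop_domain("count matrix parse error: non-integer or negative cell in ", path)
    }
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(sample_map)) {
    if (is.character(sample_map)) sample_map <- read_sample_map(sample_map)
    missing <- setdiff(colnames(m), sample_map$sample_id)
    if (length(missing)) {
      stop_domain("samples absent from the sample map: ",
                  paste(missing, collapse = ", "))
    }
  }
  count_matrix(m, class)
}

#' Construct a CountMatrix
#'
#' A thin validated container: a non-negative integer matrix (features x
#' samples) tagged with its RNA class.
#'
#' @param counts Numeric matrix with feature rownames and sample colnames.
#' @param class One of `"mRNA"`, `"lncRNA"`, `"circRNA"`, `"miRNA"`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, class) {
  class <- match.arg(class, RNA_CLASSES)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) > 0 && (any(counts < 0) || any(counts != floor(counts)))) {
    stop_domain("counts must be non-negative integers")
  }
  if (anyDuplicated(rownames(counts))) stop_domain("duplicated feature ids")
  if (anyDuplicated(colnames(counts))) stop_domain("duplicated sample ids")
  structure(list(counts = counts,
                 feature_ids = rownames(counts) %||% character(0),
                 sample_ids = colnames(counts) %||% character(0),
                 class = class),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("CountMatrix [%s]: %d features x %d samples\n",
              x$class, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Read per-sample mapped-read totals
#'
#' @param path TSV with columns `sample_id`, `mapped_total`.
#' @return Named numeric vector of totals.
#' @export
read_mapped_totals <- function(path) {
  df <- read_tsv_commented(path)
  if (!all(c("sample_id", "mapped_total") %in% names(df))) {
    stop_domain("mapped totals file must have columns sample_id and mapped_total")
  }
  tot <- as.numeric(df$mapped_total)
  if (any(is.na(tot)) || any(tot <= 0)) stop_domain("mapped totals must be positive")
  setNames(tot, as.character(df$sample_id))
}

# Shared TSV dialect: tab-separated, '#'-prefixed provenance comment lines
# before the header row.
read_tsv_commented <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, skip = "",
                                  data.table = FALSE, showProgress = FALSE))
}

write_tsv_commented <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

provenance_line <- function(stage, params) {
  paste0(stage, " | ", paste(names(params), unlist(params), sep = "=",
                             collapse = " "))
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: term id, description, member genes. A
#' description of the form `<CAT>:<free text>` with `CAT` in
#' `{BP, MF, CC, pathway}` sets the term category; anything else is labelled
#' `pathway`.
#'
#' @param path GMT file path.
#' @return A list of terms: each element has `name`, `category`, `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_domain("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  terms <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_domain("GMT parse error at line ", i, ": need term, description, >=1 gene")
    }
    desc <- f[2]
    cat_lab <- "pathway"
    if (grepl("^(BP|MF|CC|pathway):", desc)) {
      cat_lab <- sub(":.*$", "", desc)
      desc <- sub("^[^:]*:", "", desc)
    }
    terms[[f[1]]] <- list(name = desc, category = cat_lab,
                          genes = unique(f[-(1:2)]))
  }
  terms
}
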