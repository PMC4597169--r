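#' Read raw qualitative binding records from delimited text
#'
#' Reads a delimited file of HLA-peptide binding assays into a data frame of
#' raw records. Rows whose peptide contains characters outside the 20 standard
#' one-letter amino-acid codes are rejected with a warning that reports the
#' offending line numbers. Ambiguity codes (B, J, O, U, X, Z) are rejected, not
#' translated, because the downstream residue-category scheme covers only the
#' 20 standard residues.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter, default tab.
#' @param col_hla,col_peptide,col_label Names of the three required columns.
#' @param col_source Optional name of a provenance column; if absent every
#'   record gets source `"generic"`.
#' @return A data frame with columns `hla`, `peptide`, `label` (verbatim source
#'   label string) and `source`, one row per accepted record.
#' @export
read_binding_records <- function(path, delim = "\t",
                                 col_hla = "hla", col_peptide = "peptide",
                                 col_label = "label", col_source = NULL) {
  if (!file.exists(path)) stop("cannot read binding records: no such file: ", path)
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path)
    return(data.frame(hla = character(), peptide = character(),
                      label = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  for (col in c(col_hla, col_peptide, col_label)) {
    if (!col %in% names(raw)) {
      stop("required column '", col, "' not found in ", path,
           " (columns present: ", paste(names(raw), collapse = ", "), ")")
    }
  }
  out <- data.frame(
    hla = raw[[col_hla]],
    peptide = toupper(raw[[col_peptide]]),
    label = raw[[col_label]],
    source = if (!is.null(col_source) && col_source %in% names(raw))
      raw[[col_source]] else "generic",
    stringsAsFactors = FALSE
  )
  bad_pep <- !grepl(sprintf("^[%s]+$", paste(AA_STANDARD, collapse = "")), out$peptide)
  bad_hla <- !nzchar(out$hla)
  bad <- bad_pep | bad_hla
  if (any(bad)) {
    # +1 for the header line so numbers match the file as the user sees it
    warning(sum(bad), " row(s) rejected (invalid peptide or empty HLA), lines: ",
            paste(which(bad) + 1L, collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' The 20 standard amino-acid one-letter codes
#' @keywords internal
AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# Accepted source label strings, lower-cased, per source database convention.
.label_table <- list(
  IEDB = c("positive" = "positive",
           "positive-high" = "positive",
           "positive-intermediate" = "positive",
           "positive-low" = "positive",
           "negative" = "negative"),
  SYFPEITHI = c("positive" = "positive", "ligand" = "positive",
                "epitope" = "positive"),
  MHCBN = c("positive" = "positive", "negative" = "negative"),
  AntiJen = c("positive" = "positive", "negative" = "negative",
              "weak binder" = "negative", "weak-binder" = "negative"),
  generic = c("positive" = "positive", "negative" = "negative",
              "1" = "negative", "2" = "positive")
)

#' Harmonize source-specific binding labels to positive/negative
#'
#' Maps each database's qualitative grades onto a binary label: IEDB
#' positive-high/intermediate/low all count as positive, SYFPEITHI entries
#' (eluted ligands/epitopes) are positive, and AntiJen "weak binder" entries
#' are treated as negative. Generic `"positive"`/`"negative"` (and the numeric
#' weight codes 2/1) pass through.
#'
#' @param label Character vector of source label strings.
#' @param source Single source name or vector parallel to `label`; one of
#'   `"IEDB"`, `"SYFPEITHI"`, `"MHCBN"`, `"AntiJen"`, `"generic"`.
#' @return Character vector in `{"positive", "negative"}`.
#' @export
harmonize_labels <- function(label, source = "generic") {
  source <- rep_len(as.character(source), length(label))
  known <- names(.label_table)
  bad_src <- !source %in% known
  if (any(bad_src)) {
    stop("unknown source(s): ", paste(unique(source[bad_src]), collapse = ", "),
         "; accepted: ", paste(known, collapse = ", "))
  }
  out <- character(length(label))
  key <- tolower(trimws(label))
  for (src in unique(source)) {
    idx <- source == src
    tab <- .label_table[[src]]
    mapped <- tab[key[idx]]
    if (anyNA(mapped)) {
      bad <- unique(label[idx][is.na(mapped)])
      stop("unrecognized label(s) for source ", src, ": ",
           paste(bad, collapse = ", "),
           "; accepted: ", paste(names(tab), collapse = ", "))
    }
    out[idx] <- mapped
  }
  out
}

#' Normalize HLA allele names
#'
#' Upper-cases allele names, prepends the `HLA-` prefix when missing, and
#' standardizes separator usage so that the same allele written by different
#' source databases (e.g. `"A*02:01"`, `"hla-a*0201"`) deduplicates to one
#' node. Two-digit field pairs without a colon are split (`A*0201` ->
#' `A*02:01`).
#'
#' @param x Character vector of allele names.
#' @return Character vector in canonical `HLA-X*nn:nn` form where parseable;
#'   names that do not look like `locus*digits` are returned upper-cased.
#' @export
normalize_hla <- function(x) {
  y <- toupper(trimws(x))
  y <- sub("^HLA[- ]?", "", y)
  # insert colon into 4+-digit fields lacking one: A*0201 -> A*02:01
  y <- ifelse(grepl("^[A-Z]+[0-9]*\\*[0-9]{4,}$", y),
              sub("^([A-Z]+[0-9]*\\*[0-9]{2})([0-9]{2,})$", "\\1:\\2", y),
              y)
  paste0("HLA-", y)
}

#' Aggregate duplicate records by majority vote
#'
#' Collapses multiple entries for the same (HLA, peptide) pair into one record
#' carrying the proportion of positives. A pair is called positive when that
#' proportion is at least 0.5 (boundary inclusive), negative otherwise. Every
#' raw row counts once with equal weight.
#'
#' @param records Data frame with columns `hla`, `peptide` and `label` already
#'   harmonized to `"positive"`/`"negative"`.
#' @param normalize Logical; normalize allele names with [normalize_hla()]
#'   before grouping (default `TRUE`).
#' @return Data frame with one row per distinct pair and columns `hla`,
#'   `peptide`, `label`, `n_evidence`, `positive_fraction`.
#' @export
aggregate_records <- function(records, normalize = TRUE) {
  stopifnot(all(c("hla", "peptide", "label") %in% names(records)))
  if (!all(records$label %in% c("positive", "negative"))) {
    stop("labels must be harmonized to positive/negative before aggregation")
  }
  hla <- if (normalize) normalize_hla(records$hla) else records$hla
  pep <- toupper(records$peptide)
  key <- paste(hla, pep, sep = "\r")
  pos <- as.integer(records$label == "positive")
  n <- tapply(pos, key, length)
  np <- tapply(pos, key, sum)
  keys <- names(n)
  split_at <- regexpr("\r", keys, fixed = TRUE)
  frac <- as.numeric(np) / as.numeric(n)
  out <- data.frame(
    hla = substr(keys, 1L, split_at - 1L),
    peptide = substr(keys, split_at + 1L, nchar(keys)),
    label = ifelse(frac >= 0.5, "positive", "negative"),
    n_evidence = as.integer(n),
    positive_fraction = frac,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$hla, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iteratively remove sparsely connected HLAs and peptides
#'
#' Deletes every HLA and every peptide that appears in fewer than `min_count`
#' records, repeating until a fixed point: the result is the unique maximal
#' record set in which every node on either side retains at least `min_count`
#' records (the bipartite k-core with k = `min_count`). The default of 2
#' removes all singletons, which carry no information usable by a
#' neighbor-based predictor and cannot be evaluated in leave-one-out.
#'
#' @param records Deduplicated data frame with columns `hla` and `peptide`.
#' @param min_count Minimum number of records each node must retain.
#' @return The surviving subset of `records` (possibly empty), with an
#'   attribute `"filter_report"`: a data frame of per-iteration removal counts.
#' @export
degree_filter <- function(records, min_count = 2L) {
  report <- data.frame(iteration = integer(), hlas_removed = integer(),
                       peptides_removed = integer(), records_removed = integer())
  it <- 0L
  repeat {
    if (nrow(records) == 0L) break
    h_deg <- table(records$hla)
    p_deg <- table(records$peptide)
    bad_h <- names(h_deg)[h_deg < min_count]
    bad_p <- names(p_deg)[p_deg < min_count]
    if (length(bad_h) == 0L && length(bad_p) == 0L) break
    it <- it + 1L
    drop <- records$hla %in% bad_h | records$peptide %in% bad_p
    report <- rbind(report, data.frame(
      iteration = it, hlas_removed = length(bad_h),
      peptides_removed = length(bad_p), records_removed = sum(drop)))
    records <- records[!drop, , drop = FALSE]
  }
  rownames(records) <- NULL
  attr(records, "filter_report") <- report
  records
}

#' Write records as canonical three-column TSV
#'
#' Writes `hla`, `peptide` and the numeric weight code (2 = positive,
#' 1 = negative), the layout used for network exchange.
#'
#' @param records Data frame with `hla`, `peptide` and either a
#'   positive/negative `label` or a numeric `weight`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_binding_tsv <- function(records, path) {
  w <- if ("weight" %in% names(records)) as.integer(records$weight)
       else ifelse(records$label == "positive", 2L, 1L)
  utils::write.table(
    data.frame(hla = records$hla, peptide = records$peptide, label = w),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read canonical three-column binding TSV
#'
#' Inverse of [write_binding_tsv()]: reads `hla`, `peptide`, `label` with the
#' label encoded as 2 (positive) / 1 (negative) or as the words themselves.
#'
#' @param path Input file path.
#' @return Data frame with columns `hla`, `peptide`, `label`
#'   (positive/negative) and `weight` (2/1).
#' @export
read_binding_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(ncol(df) >= 3L)
  names(df)[1:3] <- c("hla", "peptide", "label")
  lab <- tolower(df$label)
  w <- ifelse(lab %in% c("2", "positive"), 2L,
              ifelse(lab %in% c("1", "negative"), 1L, NA_integer_))
  if (anyNA(w)) stop("unrecognized label values: ",
                     paste(unique(df$label[is.na(w)]), collapse = ", "))
  data.frame(hla = df$hla, peptide = toupper(df$peptide),
             label = ifelse(w == 2L, "positive", "negative"),
             weight = w, stringsAsFactors = FALSE)
}
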