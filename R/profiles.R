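#' Three-way physicochemical categories of the 20 standard residues
#'
#' The classification used throughout the module profiles: polar charged
#' (R, D, E, H, K), polar uncharged (N, C, Q, G, S, T, Y) and apolar
#' (A, I, L, M, F, P, W, V) -- 5, 7 and 8 members respectively.
#'
#' @return Named character vector mapping each one-letter code to
#'   `"polar_charged"`, `"polar_uncharged"` or `"apolar"`.
#' @export
aa_categories <- function() {
  c(R = "polar_charged", D = "polar_charged", E = "polar_charged",
    H = "polar_charged", K = "polar_charged",
    N = "polar_uncharged", C = "polar_uncharged", Q = "polar_uncharged",
    G = "polar_uncharged", S = "polar_uncharged", T = "polar_uncharged",
    Y = "polar_uncharged",
    A = "apolar", I = "apolar", L = "apolar", M = "apolar",
    F = "apolar", P = "apolar", W = "apolar", V = "apolar")
}

.check_scheme <- function(scheme) {
  if (!setequal(names(scheme), AA_STANDARD))
    stop("category scheme must cover exactly the 20 standard residues")
  scheme
}

.length_bucket <- function(len) {
  b <- ifelse(len > 11L, ">11", as.character(len))
  factor(b, levels = c(sort(unique(len[len <= 11L])), if (any(len > 11L)) ">11"))
}

#' Peptide length distribution per module
#'
#' Counts peptides per module and length bucket (7-, 8-, ..., 11-mer, with
#' all lengths above 11 pooled into one ">11" bucket) and the column-wise
#' percentages: each length column sums to 100% over the modules, showing
#' where peptides of that length concentrate.
#'
#' @param partition A `module_partition` covering all peptide nodes.
#' @param net The [binding_network()] the partition was computed on.
#' @return Object of class `"profile_table"`: list with `counts` and
#'   `percent` matrices (modules x length buckets, plus a Total row/column)
#'   and `hla_count` per module.
#' @export
length_distribution <- function(partition, net) {
  pep <- net$peptide
  mod <- partition$peptide_module[pep]
  if (anyNA(mod)) stop("partition does not cover every peptide node")
  buck <- .length_bucket(nchar(pep))
  counts <- table(module = mod, length = buck)
  counts_m <- matrix(as.integer(counts), nrow = nrow(counts),
                     dimnames = dimnames(counts))
  col_tot <- colSums(counts_m)
  pct <- sweep(counts_m, 2, pmax(col_tot, 1), "/") * 100
  hla_count <- table(factor(partition$hla_module,
                            levels = rownames(counts_m)))
  structure(list(
    counts = cbind(counts_m, Total = rowSums(counts_m)),
    percent = pct,
    column_totals = col_tot,
    hla_count = as.integer(hla_count)), class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  cat("Peptides per module and length (column % in parentheses)\n")
  m <- x$counts
  print(m)
  cat("HLAs per module:", paste(x$hla_count, collapse = ", "), "\n")
  invisible(x)
}

#' Position-wise residue-category profile of equal-length peptides
#'
#' For peptides of one fixed length, the fraction of each physicochemical
#' category at every position; fractions sum to 1 per position. This is the
#' per-module anchor-position readout (P2 and the C-terminal position carry
#' the classical binding-motif signal).
#'
#' @param peptides Character vector of peptides, all of length `length`.
#' @param length Expected peptide length (default 9).
#' @param scheme Category scheme, default [aa_categories()].
#' @return Matrix (3 categories x positions) of fractions.
#' @export
position_category_profile <- function(peptides, length = 9L,
                                      scheme = aa_categories()) {
  scheme <- .check_scheme(scheme)
  if (any(nchar(peptides) != length))
    stop("all peptides must have length ", length)
  cats <- sort(unique(scheme))
  m <- matrix(0, nrow = length(cats), ncol = length,
              dimnames = list(cats, paste0("P", seq_len(length))))
  if (length(peptides) == 0L) return(m)
  chars <- matrix(unlist(strsplit(peptides, "")), ncol = length, byrow = TRUE)
  for (j in seq_len(length)) {
    tab <- table(factor(scheme[chars[, j]], levels = cats))
    m[, j] <- as.numeric(tab) / length(peptides)
  }
  m
}

#' Read a gapless HLA alignment from FASTA
#'
#' Expects equal-length, gap-free sequences of the Class I peptide-binding
#' region (residues 2-182 of the mature chain), named by allele.
#'
#' @param path FASTA file path.
#' @return Named character vector of aligned sequences.
#' @export
read_hla_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(ss))
  if (length(unique(nchar(seqs))) > 1L)
    stop("alignment rows have unequal lengths")
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("alignment must be gapless")
  seqs
}

#' Read a contact-residue map (peptide position -> HLA residue numbers)
#'
#' Two-column TSV: `peptide_position` (1-9) and `residues`, a comma-separated
#' list of HLA residue numbers in the 1-based mature-chain numbering of
#' A*02:01 (PDB 3HLA). Lines starting with `#` are comments.
#'
#' @param path TSV path; defaults to the reconstructed pocket-residue map
#'   shipped with the package (see [default_contact_map()]).
#' @return Named list: element `"1"`.."9"` -> sorted integer residue numbers.
#' @export
read_contact_map <- function(path = NULL) {
  if (is.null(path)) return(default_contact_map())
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  names(df)[1:2] <- c("peptide_position", "residues")
  out <- lapply(df$residues, function(s)
    sort(as.integer(strsplit(s, ",")[[1]])))
  names(out) <- df$peptide_position
  if (any(lengths(out) == 0L)) stop("empty residue list in contact map")
  out
}

#' The shipped contact-residue map (reconstructed)
#'
#' Pocket-lining residues of the Class I groove contacting each position of a
#' 9-mer peptide, in A*02:01 mature-chain numbering. These lists are a
#' reconstruction assembled from the classical A-F pocket literature, not a
#' verbatim copy of any single published table; users with a preferred
#' contact definition (e.g. NetMHCpan pseudo-sequence positions) should
#' supply their own file to [read_contact_map()].
#'
#' @return Named list, peptide position -> integer residue numbers.
#' @export
default_contact_map <- function() {
  read_contact_map(system.file("extdata", "contact_residues_9mer_reconstructed.tsv",
                               package = "hlanet", mustWork = TRUE))
}

#' Extract position-specific pseudo-sequences from an alignment
#'
#' Concatenates, for every allele, the residues at the contact positions for
#' one peptide position, in ascending residue-number order. Alignment rows
#' cover mature-chain residues 2-182, so row index i maps to residue number
#' i + 1.
#'
#' @param alignment Named character vector from [read_hla_alignment()].
#' @param contact_map List from [read_contact_map()].
#' @param peptide_position Which peptide position's contacts to use (1-9).
#' @param region_start First mature-chain residue covered by the alignment
#'   (default 2).
#' @return Named character vector of pseudo-sequences, one per allele.
#' @export
extract_pseudo_sequences <- function(alignment, contact_map, peptide_position,
                                     region_start = 2L) {
  key <- as.character(peptide_position)
  if (!key %in% names(contact_map))
    stop("no contact residues for peptide position ", peptide_position)
  res <- contact_map[[key]]
  if (length(res) == 0L) stop("empty contact list for position ", peptide_position)
  width <- unique(nchar(alignment))
  idx <- res - region_start + 1L
  bad <- idx < 1L | idx > width
  if (any(bad))
    stop("contact residue(s) outside the aligned region: ",
         paste(res[bad], collapse = ", "))
  vapply(alignment, function(s)
    paste(substring(s, idx, idx), collapse = ""), character(1))
}

#' Fraction of identical positions between two equal-length sequences
#'
#' @param seq_a,seq_b Equal-length (gapless, pre-aligned) sequences.
#' @return Identity fraction in \[0, 1\]; symmetric, 1 iff equal.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must have equal length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  mean(a == b)
}

#' Within- vs between-module pseudo-sequence identity
#'
#' For each module with at least two HLAs, compares the pairwise identities
#' among its alleles (within pairs) against the identities of pairs
#' straddling the module boundary (one endpoint inside, one outside), with a
#' two-sample test per module. Pair identities are not independent
#' observations, so the label-permutation test is offered alongside the
#' default rank test.
#'
#' @param partition A `module_partition` (only `hla_module` is used), or a
#'   named integer vector of module ids.
#' @param pseudo_sequences Named character vector (alleles matching the
#'   partition names).
#' @param test `"wilcoxon"` (Mann-Whitney on pair identities, default) or
#'   `"permutation"` (re-randomize module labels, compare mean within-between
#'   difference).
#' @param n_perm Permutation count for `test = "permutation"`.
#' @param seed Seed for the permutation test.
#' @return Data frame: module, n_hla, mean_within, mean_between, p_value.
#'   Modules with a single HLA get `NA` means/p and are excluded from
#'   testing; a degenerate comparison (all identities equal) reports `NA` p.
#' @export
within_between_identity <- function(partition, pseudo_sequences,
                                    test = c("wilcoxon", "permutation"),
                                    n_perm = 999L, seed = 1L) {
  test <- match.arg(test)
  mod <- if (inherits(partition, "module_partition")) partition$hla_module
         else partition
  alleles <- intersect(names(mod), names(pseudo_sequences))
  if (length(alleles) < 2L) stop("need at least two HLAs with sequences")
  mod <- mod[alleles]
  seqs <- pseudo_sequences[alleles]
  n <- length(alleles)
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    idm[i, j] <- idm[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
  }
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  pair_id <- idm[cbind(pair_i, pair_j)]

  stat_for <- function(mm) {
    vapply(sort(unique(mm)), function(m) {
      wi <- mm[pair_i] == m & mm[pair_j] == m
      bt <- xor(mm[pair_i] == m, mm[pair_j] == m)
      if (!any(wi) || !any(bt)) return(NA_real_)
      mean(pair_id[wi]) - mean(pair_id[bt])
    }, numeric(1))
  }

  mods <- sort(unique(mod))
  out <- data.frame(module = mods, n_hla = as.integer(table(mod)[as.character(mods)]),
                    mean_within = NA_real_, mean_between = NA_real_,
                    p_value = NA_real_)
  if (test == "permutation") {
    set.seed(seed)
    real <- stat_for(mod)
    perm <- replicate(n_perm, stat_for(sample(mod)))
    if (is.null(dim(perm))) perm <- matrix(perm, nrow = 1)
  }
  for (r in seq_along(mods)) {
    m <- mods[r]
    wi <- mod[pair_i] == m & mod[pair_j] == m
    bt <- xor(mod[pair_i] == m, mod[pair_j] == m)
    if (!any(wi)) next   # single-HLA module: within mean undefined
    out$mean_within[r] <- mean(pair_id[wi])
    out$mean_between[r] <- if (any(bt)) mean(pair_id[bt]) else NA_real_
    if (!any(bt)) next
    w_vals <- pair_id[wi]; b_vals <- pair_id[bt]
    if (length(unique(c(w_vals, b_vals))) == 1L) next  # degenerate: NA p
    out$p_value[r] <- if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(w_vals, b_vals,
                                          alternative = "greater")$p.value)
    } else {
      (1 + sum(perm[r, ] >= real[r], na.rm = TRUE)) / (1 + sum(!is.na(perm[r, ])))
    }
  }
  out
}

#' Annotate residues that differ from the column mode
#'
#' For each alignment column, the most frequent residue (ties broken toward
#' the alphabetically smallest) is treated as the background and blanked;
#' every other residue is reported with its physicochemical category -- the
#' data behind a module-colored alignment-difference plot.
#'
#' @param alignment Named character vector of equal-length gapless sequences.
#' @param scheme Category scheme, default [aa_categories()].
#' @param region_start Mature-chain residue number of the first column
#'   (default 2), used for the reported `position`.
#' @return Data frame: `allele`, `position` (residue number), `residue`,
#'   `category`.
#' @export
highlight_nonmodal_residues <- function(alignment, scheme = aa_categories(),
                                        region_start = 2L) {
  scheme <- .check_scheme(scheme)
  width <- unique(nchar(alignment))
  if (length(width) != 1L) stop("alignment rows have unequal lengths")
  chars <- matrix(unlist(strsplit(alignment, "")), ncol = width, byrow = TRUE)
  rows <- list()
  for (j in seq_len(width)) {
    tab <- table(chars[, j])
    modal <- sort(names(tab)[tab == max(tab)])[1]   # lowest-alphabetical tie-break
    off <- which(chars[, j] != modal)
    if (length(off)) {
      rows[[length(rows) + 1L]] <- data.frame(
        allele = names(alignment)[off],
        position = j + region_start - 1L,
        residue = chars[off, j],
        category = unname(scheme[chars[off, j]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(allele = character(), position = integer(),
                      residue = character(), category = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
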