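#' Relative expression by the delta-delta-Ct method
#'
#' Computes per-condition dCt = mean Ct(target) - mean Ct(reference gene)
#' (replicates aggregated by arithmetic mean), then
#' ddCt = dCt(control) - dCt(condition) and returns the fold change
#' 2^(-ddCt). Note the sign convention: the control dCt comes first in the
#' subtraction, so with fold = 2^(-ddCt) a condition whose target Ct rises
#' relative to the control (less transcript) yields a fold change above 1
#' under this convention; it is implemented exactly as stated and
#' documented rather than flipped to the more common
#' dCt(condition) - dCt(control) form.
#'
#' @param ct_table data frame with columns `sample`, `gene`, `ct` (one row
#'   per replicate well; technical replicates share `sample` and `gene`).
#' @param target_gene gene to quantify.
#' @param condition sample/condition name to compare against the control.
#' @param control_condition name of the control sample.
#' @param reference_gene housekeeping gene used for normalization
#'   (default `"RPL37A"`).
#' @return list with `d_ct_control`, `d_ct_condition`, `dd_ct`,
#'   `fold_change`.
#' @export
#' @examples
#' ct <- data.frame(
#'   sample = rep(c("ctrl", "treated"), each = 4),
#'   gene = rep(c("CTGF", "CTGF", "RPL37A", "RPL37A"), 2),
#'   ct = c(24, 24.2, 20, 20.1, 26, 26.1, 20, 20.2))
#' ddct_fold_change(ct, "CTGF", "treated", "ctrl")$fold_change
ddct_fold_change <- function(ct_table, target_gene, condition,
                             control_condition,
                             reference_gene = "RPL37A") {
  stopifnot(is.data.frame(ct_table),
            all(c("sample", "gene", "ct") %in% names(ct_table)))
  if (!all(is.finite(ct_table$ct))) stop("Ct values must be finite")
  mean_ct <- function(smp, gene) {
    v <- ct_table$ct[ct_table$sample == smp & ct_table$gene == gene]
    if (!length(v))
      stop(sprintf("no Ct values for gene '%s' in sample '%s'%s", gene, smp,
                   if (gene == reference_gene) " (reference gene missing)" else ""))
    mean(v)
  }
  d_ct <- function(smp) mean_ct(smp, target_gene) - mean_ct(smp, reference_gene)
  d_ctrl <- d_ct(control_condition)
  d_cond <- d_ct(condition)
  dd <- d_ctrl - d_cond
  list(d_ct_control = d_ctrl, d_ct_condition = d_cond, dd_ct = dd,
       fold_change = 2^(-dd))
}

#' Normalize co-immunoprecipitation densitometry
#'
#' For each condition the raw relative binding is the co-precipitated
#' TEAD band signal divided by the Flag-per-IgG signal
#' (`tead / (flag / igg)`); values are then normalized to the positive
#' control so the positive control reads 1.
#'
#' @param records data frame with columns `condition`, `tead_signal`,
#'   `flag_signal`, `igg_signal` (all > 0).
#' @param positive_control_condition condition used as the normalizer.
#' @return data frame with `condition`, `raw`, `relative_binding`.
#' @export
coip_normalize <- function(records, positive_control_condition) {
  stopifnot(is.data.frame(records),
            all(c("condition", "tead_signal", "flag_signal", "igg_signal")
                %in% names(records)))
  if (any(records$flag_signal <= 0) || any(records$igg_signal <= 0))
    stop("flag and IgG band signals must be positive")
  if (!positive_control_condition %in% records$condition)
    stop("positive control condition '", positive_control_condition,
         "' not present")
  raw <- records$tead_signal / (records$flag_signal / records$igg_signal)
  pos <- mean(raw[records$condition == positive_control_condition])
  data.frame(condition = records$condition, raw = raw,
             relative_binding = raw / pos)
}

#' Normalize firefly luciferase activity to the Renilla internal control
#'
#' @param firefly firefly luciferase activity (reporter).
#' @param renilla Renilla luciferase activity (internal control, > 0).
#' @return firefly / renilla.
#' @export
luciferase_normalize <- function(firefly, renilla) {
  if (any(renilla <= 0)) stop("Renilla activity must be positive")
  firefly / renilla
}

#' Classify spread cells by surface area
#'
#' Splits cell surface areas at a cutoff (120 um^2 by default); areas
#' exactly at the cutoff count as "below" (documented tie-break).
#'
#' @param areas numeric vector of cell areas in um^2.
#' @param cutoff area cutoff in um^2 (> 0), default 120.
#' @return named numeric vector `c(fraction_below, fraction_above)`;
#'   the two fractions sum to 1.
#' @export
spreading_classify <- function(areas, cutoff = 120) {
  if (!length(areas)) stop("empty area list")
  if (cutoff <= 0) stop("cutoff must be positive")
  below <- mean(areas <= cutoff)
  c(fraction_below = below, fraction_above = 1 - below)
}

#' Design alanine-cassette scanning mutants
#'
#' Tiles a residue interval with consecutive cassettes of alanines: mutant
#' i substitutes residues `start + (i-1)*L` .. `start + i*L - 1` with
#' `L = cassette_len` alanines, leaving all other residues unchanged. The
#' cassettes tile the region exactly, so the region length must be
#' divisible by the cassette length.
#'
#' @param sequence one-letter amino-acid string (standard 20-letter
#'   alphabet), or a length-1 named character vector.
#' @param start,end 1-based inclusive residue interval to scan.
#' @param cassette_len cassette length in residues; default 7.
#' @return named character vector of mutant sequences (`A1`, `A2`, ...).
#' @export
#' @examples
#' mut <- alanine_cassette_mutants(strrep("G", 60), start = 11, end = 24,
#'                                 cassette_len = 7)
#' names(mut)  # "A1" "A2"
alanine_cassette_mutants <- function(sequence, start, end, cassette_len = 7L) {
  seq_chr <- as.character(sequence)[1]
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seq_chr))
    stop("sequence must use the 20 standard one-letter amino-acid codes")
  n <- nchar(seq_chr)
  if (start < 1 || end > n || start > end)
    stop(sprintf("interval %d-%d outside sequence of length %d", start, end, n))
  len <- end - start + 1L
  if (len %% cassette_len != 0L)
    stop(sprintf("region length %d is not divisible by cassette length %d",
                 len, cassette_len))
  k <- len %/% cassette_len
  out <- character(k)
  for (i in seq_len(k)) {
    s <- start + (i - 1L) * cassette_len
    e <- s + cassette_len - 1L
    mut <- seq_chr
    substr(mut, s, e) <- strrep("A", cassette_len)
    out[i] <- mut
  }
  names(out) <- paste0("A", seq_len(k))
  attr(out, "cassette_intervals") <- data.frame(
    name = names(out),
    start = start + (seq_len(k) - 1L) * cassette_len,
    end = start + seq_len(k) * cassette_len - 1L)
  out
}

#' Length of a 1-based inclusive residue interval
#'
#' @param start,end 1-based inclusive residue indices (`start <= end`).
#' @return `end - start + 1`.
#' @export
#' @examples
#' interval_length(376, 424)  # the alpha9 helix: 49 residues
interval_length <- function(start, end) {
  if (start < 1 || start > end) stop("need 1 <= start <= end")
  end - start + 1
}

#' Registry of GBP-1 expression constructs
#'
#' The eight named GBP-1 sub-fragments used in the structure-function
#' dissection, as 1-based inclusive residue intervals of the full-length
#' protein: the globular GTPase domain, the helical domain, and the
#' helix-bounded fragments including the alpha9 helix (376-424) whose
#' N-terminal seven residues (376-382, VDHLFQK) carry the TEAD-binding
#' motif.
#'
#' @param name optional construct name to look up (aliases with Greek
#'   alpha, case and dash variants are accepted, e.g. `"α9"` == `"a9"`).
#' @return with `name`: a one-row data frame; without: the full registry
#'   data frame (`name`, `start`, `end`, `length`).
#' @export
#' @examples
#' fragment_registry("a9")       # 376 424
#' fragment_registry("Glo")      # 1 290
#' nrow(fragment_registry())     # 8
fragment_registry <- function(name = NULL) {
  reg <- data.frame(
    name = c("Glo", "Hel", "a7-11", "a7-9", "a9-11", "a12-13", "a9", "a7-13"),
    start = c(1L, 291L, 311L, 311L, 376L, 484L, 376L, 311L),
    end = c(290L, 592L, 478L, 424L, 478L, 582L, 424L, 582L)
  )
  reg$length <- reg$end - reg$start + 1L
  if (is.null(name)) return(reg)
  key <- tolower(gsub("α", "a", name))
  key <- gsub("[‐-―−]", "-", key)   # unify dash variants
  key <- gsub("\\s", "", key)
  hit <- match(key, tolower(reg$name))
  if (is.na(hit))
    stop("unknown construct '", name, "'; known: ",
         paste(reg$name, collapse = ", "))
  reg[hit, , drop = FALSE]
}

#' Read / write protein sequences as FASTA
#'
#' Thin wrappers around Biostrings for the plain-text FASTA exchange of
#' fragment and mutant sequences.
#'
#' @param path FASTA file path.
#' @param sequences named character vector of amino-acid sequences.
#' @return `read_fasta_sequences` returns a named character vector;
#'   `write_fasta_sequences` invisibly returns `path`.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta_sequences
#' @export
write_fasta_sequences <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
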