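AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Per-column conservation profile of a protein alignment
#'
#' Computes per-column amino-acid frequencies (20 letters plus gap) and the
#' information content IC = log2(20) - H, with the Shannon entropy H (bits)
#' taken over the 20 amino-acid frequencies renormalised among non-gap
#' characters; the gap fraction is reported separately. A fully conserved
#' column scores log2(20) ~ 4.32 bits, a uniform column 0. No small-sample
#' correction is applied by default.
#'
#' @param msa Path to an aligned FASTA file, a `Biostrings::AAStringSet`, or
#'   a character vector of equal-length sequences.
#' @param pseudocount Pseudocount added to every amino-acid count.
#' @return Tibble of class `pa_conservation_profile` with `position`, `ic`
#'   (bits), `gap_frac`, `consensus`; attribute `freq` (position x 21
#'   frequency matrix including the gap column).
#' @export
column_profile <- function(msa, pseudocount = 0) {
  seqs <- if (inherits(msa, "AAStringSet")) as.character(msa)
    else if (is.character(msa) && length(msa) == 1 && file.exists(msa))
      as.character(Biostrings::readAAStringSet(msa))
    else as.character(msa)
  if (length(seqs) < 1) stop("empty alignment")
  L <- unique(nchar(seqs))
  if (length(L) != 1) {
    stop("ragged alignment: sequence lengths ", paste(sort(L), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  mat[mat == "."] <- "-"
  freq <- matrix(0, nrow = L, ncol = 21,
                 dimnames = list(NULL, c(AA_ALPHABET, "-")))
  ic <- numeric(L); gap_frac <- numeric(L); consensus <- character(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    counts <- table(factor(col, levels = c(AA_ALPHABET, "-")))
    freq[j, ] <- counts / sum(counts)
    gap_frac[j] <- freq[j, "-"]
    aa_counts <- counts[AA_ALPHABET] + pseudocount
    tot <- sum(aa_counts)
    if (tot == 0) {
      ic[j] <- NA_real_; consensus[j] <- "-"
      next
    }
    p <- as.numeric(aa_counts) / tot
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    ic[j] <- log2(20) - h
    consensus[j] <- AA_ALPHABET[which.max(p)]
  }
  out <- tibble::tibble(position = seq_len(L), ic = ic, gap_frac = gap_frac,
                        consensus = consensus)
  attr(out, "freq") <- freq
  attr(out, "n_seqs") <- length(seqs)
  class(out) <- c("pa_conservation_profile", class(out))
  out
}

#' Locate variable positions inside conserved patches
#'
#' Nominates positions of low information content whose surrounding window
#' (self excluded, truncated at the alignment ends) is on average highly
#' conserved - nonconserved islands in a conserved region.
#'
#' @param profile A [column_profile()] result.
#' @param window Odd window width (positions).
#' @param ic_high Minimum window-mean IC (bits) for the surroundings.
#' @param ic_low Maximum IC (bits) for the island position itself.
#' @return Tibble with `position`, `ic`, `window_ic`.
#' @export
variable_in_conserved <- function(profile, window = 9, ic_high = 3.0,
                                  ic_low = 1.0) {
  if (window %% 2 != 1) stop("window must be odd")
  L <- nrow(profile)
  if (window > L) stop("window (", window, ") larger than alignment (", L, ")")
  half <- (window - 1) / 2
  ic <- profile$ic
  win_ic <- vapply(seq_len(L), function(j) {
    lo <- max(1, j - half); hi <- min(L, j + half)
    nb <- setdiff(lo:hi, j)
    mean(ic[nb], na.rm = TRUE)
  }, 0)
  out <- tibble::tibble(position = profile$position, ic = ic,
                        window_ic = win_ic)
  out[!is.na(ic) & ic <= ic_low & win_ic >= ic_high, ]
}

#' Export a logo matrix (position x residue frequency) as TSV
#'
#' The output is consumable by standard sequence-logo plotters.
#'
#' @param profile A [column_profile()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(profile, path) {
  freq <- attr(profile, "freq")
  df <- data.frame(position = profile$position,
                   freq[, AA_ALPHABET, drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
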