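# ---------------------------------------------------------------------------
# Quantitative logic behind bench validation of a called target: IUPAC core
# motif scanning of promoters and EMSA probes, ChIP-qPCR tiling-window
# design, and percent-input enrichment.
# ---------------------------------------------------------------------------

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Scan a sequence for an IUPAC motif
#'
#' Reports every exact IUPAC-consensus match in ascending position;
#' overlapping matches are allowed.  With `both_strands`, matches of the
#' motif's reverse complement are reported on the `-` strand at
#' forward-strand coordinates (so downstream joins live in one coordinate
#' frame).  `N` in the scanned sequence never matches.
#'
#' @param seq A single sequence: character string over `{A,C,G,T,N}`
#'   (case-insensitive; may be named).
#' @param motif IUPAC consensus string, e.g. `"TTTCCT"`.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return A `data.frame` with columns `position` (0-based offset of the
#'   match start in forward coordinates), `strand`, `matched` (the
#'   forward-strand subsequence).
#' @examples
#' scan_motif("TCAACTCAAAGTTTCCTCTCCTCCAGG", "TTTCCT")  # one + hit at 11
#' @export
scan_motif <- function(seq, motif, both_strands = TRUE) {
  stopifnot(length(seq) == 1, length(motif) == 1)
  seq <- toupper(seq)
  motif <- toupper(motif)
  if (grepl("[^ACGTN]", seq)) stop("sequence letters must be in {A,C,G,T,N}")
  if (!all(strsplit(motif, "")[[1]] %in% IUPAC_LETTERS)) {
    stop("invalid IUPAC symbol in motif '", motif, "'")
  }
  if (!nchar(seq) || !nchar(motif)) stop("empty sequence or motif")
  subj <- Biostrings::DNAString(seq)
  hit_df <- function(pattern, strand_label) {
    # fixed = "subject": IUPAC codes in the pattern act as wildcards while
    # subject letters stay literal, so subject N cannot satisfy a match.
    m <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
    if (!length(m)) {
      return(data.frame(position = integer(0), strand = character(0),
                        matched = character(0), stringsAsFactors = FALSE))
    }
    pos <- BiocGenerics::start(m) - 1
    matched <- as.character(m)
    keep <- !grepl("N", matched, fixed = TRUE)
    data.frame(position = pos[keep],
               strand = rep(strand_label, sum(keep)),
               matched = matched[keep], stringsAsFactors = FALSE)
  }
  hits <- hit_df(motif, "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    # a self-reverse-complementary motif would duplicate every forward hit
    if (rc != motif) hits <- rbind(hits, hit_df(rc, "-"))
  }
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan many sequences for a motif
#'
#' @param seqs Named character vector (e.g. from [read_fasta()]).
#' @inheritParams scan_motif
#' @return A `data.frame` with columns `seq_id`, `position`, `strand`,
#'   `matched`.
#' @export
scan_motif_set <- function(seqs, motif, both_strands = TRUE) {
  out <- lapply(seq_along(seqs), function(i) {
    h <- scan_motif(seqs[[i]], motif, both_strands)
    if (nrow(h)) cbind(seq_id = names(seqs)[i], h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(0), position = integer(0),
                      strand = character(0), matched = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Tile a TSS-relative region into qPCR amplicon windows
#'
#' Left-aligned, consecutive, non-overlapping windows; the last window is
#' truncated when `width` does not divide the span.  Tiling the canonical
#' promoter region −5000..0 at the default 500 bp yields the familiar ten
#' primer-pair design.
#'
#' @param region_start,region_end Signed bp relative to the TSS,
#'   `region_start < region_end` (equal gives an empty tiling).
#' @param width Window width in bp (default 500).
#' @return A `data.frame` with columns `start`, `end` (half-open,
#'   TSS-relative) and `label` (`win_1`, ...).
#' @examples
#' tiling_windows(-5000, 0)          # 10 windows of 500 bp
#' tiling_windows(-5000, 0, 600)     # 9 windows, last of width 200
#' @export
tiling_windows <- function(region_start, region_end, width = 500) {
  if (width <= 0) stop("width must be positive")
  if (region_start > region_end) stop("region_start must be <= region_end")
  if (region_start == region_end) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  starts <- seq(region_start, region_end - 1, by = width)
  ends <- pmin(starts + width, region_end)
  data.frame(start = starts, end = ends,
             label = paste0("win_", seq_along(starts)),
             stringsAsFactors = FALSE)
}

#' Percent-input ChIP-qPCR enrichment
#'
#' The input Ct is first adjusted to a 100% input equivalent by subtracting
#' `log2(1 / input_fraction)` (e.g. log2(100) cycles for a 1% input
#' aliquot), then the IP signal is expressed relative to it:
#' \deqn{\%input = 100 \times 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}}
#'
#' @param ct_ip IP-sample Ct (cycles); vectorised.
#' @param ct_input Input-sample Ct (cycles).
#' @param input_fraction Fraction of chromatin used as input, in (0, 1]
#'   (default 0.01, i.e. 1% input).
#' @return Percent input (numeric).  Values above 100 are possible only for
#'   pathological inputs and trigger a warning.
#' @examples
#' percent_input(25 - log2(100), 25)  # 100 by construction
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction = 0.01) {
  stopifnot(is.numeric(ct_ip), is.numeric(ct_input))
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]")
  }
  adj_input <- ct_input - log2(1 / input_fraction)
  res <- 100 * 2^(adj_input - ct_ip)
  if (any(res > 100)) {
    warning("percent input above 100% for ", sum(res > 100),
            " measurement(s); check Ct values and input fraction")
  }
  res
}

#' Fold enrichment of antibody over IgG control
#'
#' @param ab Percent input of the specific-antibody IP.
#' @param igg Percent input of the matched IgG control (must be > 0).
#' @return `ab / igg`.
#' @examples
#' enrichment_vs_control(2, 0.5)  # 4
#' @export
enrichment_vs_control <- function(ab, igg) {
  if (any(igg <= 0)) stop("IgG percent input must be positive")
  ab / igg
}

#' Percent input from a Ct table
#'
#' @param tab Data frame with columns `ct_ip`, `ct_input`,
#'   `input_fraction`, and optionally `label`.
#' @return The table with a `percent_input` column appended.
#' @export
percent_input_table <- function(tab) {
  stopifnot(all(c("ct_ip", "ct_input", "input_fraction") %in% names(tab)))
  tab$percent_input <- percent_input(tab$ct_ip, tab$ct_input,
                                     tab$input_fraction)
  tab
}
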