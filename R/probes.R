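# In-silico FISH probe evaluation: minimal Hamming mismatch counting of an
# oligonucleotide probe against 16S target sequences. Hybridization is
# modelled as ungapped pairing of the probe with the target, i.e. the
# reverse complement of the probe is slid along the target and compared
# window by window; both target strands are scanned.

# IUPAC nucleotide codes as 4-bit sets over (A, C, G, T/U).
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- IUPAC_BITS[chars]
  if (anyNA(codes)) {
    stop("sequence contains non-IUPAC characters: ",
         paste(unique(chars[is.na(codes)]), collapse = ", "), call. = FALSE)
  }
  unname(codes)
}

#' Reverse complement of an IUPAC DNA sequence
#'
#' @param seq character scalar in the IUPAC DNA alphabet.
#' @return the reverse complement, uppercase.
#' @export
reverse_complement <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  comp <- IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) stop("sequence contains non-IUPAC characters", call. = FALSE)
  paste(rev(unname(comp)), collapse = "")
}

#' Define an oligonucleotide FISH probe
#'
#' @param name probe name.
#' @param seq probe sequence 5'->3' in IUPAC DNA codes, length >= 10.
#' @return an object of class `oligo_probe`.
#' @export
oligo_probe <- function(name, seq) {
  seq <- toupper(seq)
  codes <- encode_seq(seq)
  if (length(codes) < 10L) stop("probe must be at least 10 nt", call. = FALSE)
  structure(list(name = name, seq = seq, length = length(codes)),
            class = "oligo_probe")
}

#' @export
print.oligo_probe <- function(x, ...) {
  cat(sprintf("<oligo_probe> %s: 5'-%s-3' (%d nt)\n", x$name, x$seq, x$length))
  invisible(x)
}

# Mismatch count of `query` (encoded) against every window of `target`
# (encoded). Two codes pair when their base sets intersect; in strict mode
# only identical unambiguous bases pair.
window_mismatches <- function(query, target, strict = FALSE) {
  k <- length(query)
  nw <- length(target) - k + 1L
  if (nw < 1L) return(integer(0))
  mism <- integer(nw)
  for (i in seq_len(k)) {
    tw <- target[i:(i + nw - 1L)]
    if (strict) {
      unambig <- query[i] %in% c(1L, 2L, 4L, 8L) & tw %in% c(1L, 2L, 4L, 8L)
      mism <- mism + as.integer(!(unambig & tw == query[i]))
    } else {
      mism <- mism + as.integer(bitwAnd(query[i], tw) == 0L)
    }
  }
  mism
}

#' Minimal mismatch count of a probe against one target sequence
#'
#' Slides the reverse complement of the probe along the target without gaps
#' and counts base mismatches per window; both strands of the target are
#' scanned and the global minimum is reported. By default IUPAC ambiguity
#' codes pair whenever their base sets intersect (an `N` in the target pairs
#' with any probe base); `strict = TRUE` counts any ambiguity as a mismatch.
#'
#' @param probe an [oligo_probe()] or a character probe sequence (5'->3').
#' @param target target sequence (character scalar), length >= probe length.
#' @param target_id identifier carried into the result.
#' @param strict logical; see above.
#' @return one-row data frame: `target_id`, `min_mismatches`, `position`
#'   (1-based window start on the reported strand), `strand` (`"+"` scans
#'   the target as given, `"-"` its reverse complement), `probe_length`.
#' @examples
#' min_mismatches("GCCTTCCCACATCGTTT", paste0("AAAA",
#'   reverse_complement("GCCTTCCCACATCGTTT"), "AAAA"))
#' @export
min_mismatches <- function(probe, target, target_id = "target",
                           strict = FALSE) {
  if (inherits(probe, "oligo_probe")) probe <- probe$seq
  query <- encode_seq(reverse_complement(probe))
  k <- length(query)
  tfwd <- encode_seq(target)
  if (length(tfwd) < k) {
    stop("target is shorter than the probe", call. = FALSE)
  }
  trev <- encode_seq(reverse_complement(target))
  best <- NULL
  for (strand in c("+", "-")) {
    tgt <- if (strand == "+") tfwd else trev
    mism <- window_mismatches(query, tgt, strict = strict)
    i <- which.min(mism)
    if (is.null(best) || mism[i] < best$min_mismatches) {
      best <- list(min_mismatches = mism[i], position = i, strand = strand)
    }
  }
  data.frame(target_id = target_id, min_mismatches = best$min_mismatches,
             position = best$position, strand = best$strand,
             probe_length = k, stringsAsFactors = FALSE)
}

#' Screen a probe against a set of 16S target sequences
#'
#' Applies [min_mismatches()] to every target and counts how many targets a
#' probe is expected to detect, using the strict comparison
#' `min_mismatches < threshold` (a target with exactly `threshold` mismatches
#' does not pass).
#'
#' @param probe an [oligo_probe()] or character probe sequence.
#' @param targets named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param threshold mismatch threshold for the pass flag (default 5).
#' @param strict passed to [min_mismatches()].
#' @return data frame with one row per target (columns of
#'   [min_mismatches()] plus `passes`); the number of passing targets is
#'   attached as attribute `n_pass`.
#' @export
screen_probe <- function(probe, targets, threshold = 5, strict = FALSE) {
  if (is.character(targets) && length(targets) == 1L &&
      file.exists(targets) && !grepl("^[ACGTURYSWKMBDHVN]+$",
                                     toupper(targets))) {
    targets <- Biostrings::readDNAStringSet(targets)
  }
  if (inherits(targets, "DNAStringSet")) {
    targets <- setNames(as.character(targets), names(targets))
  }
  if (length(targets) == 0L) stop("no target sequences supplied", call. = FALSE)
  if (is.null(names(targets)) || any(names(targets) == "")) {
    names(targets) <- paste0("target_", seq_along(targets))
  }
  rows <- lapply(names(targets), function(id) {
    min_mismatches(probe, targets[[id]], target_id = id, strict = strict)
  })
  out <- do.call(rbind, rows)
  out$passes <- out$min_mismatches < threshold
  attr(out, "n_pass") <- sum(out$passes)
  attr(out, "threshold") <- threshold
  out
}
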