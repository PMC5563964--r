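#' Simulate 16S target sequences with planned probe mismatch counts
#'
#' Constructs, for each requested mismatch count m, a random target sequence
#' containing exactly one best-matching window whose Hamming distance to the
#' reverse complement of the probe equals m, with every other window (on both
#' strands) strictly worse. Construction is by planting a mutated copy of the
#' probe's reverse complement in a random background and verifying the
#' planted window is the unique optimum by a full scan; failures are
#' regenerated.
#'
#' @param probe an [oligo_probe()] or character probe sequence (plain ACGT).
#' @param mismatch_counts integer vector; planned minimal mismatch count per
#'   target. Each must be <= the probe length.
#' @param target_length length of each target sequence (default 300 nt).
#' @param seed integer seed; output is reproducible.
#' @param max_tries construction attempts per target before giving up.
#' @return named character vector of target sequences
#'   (`planned_<m>_<i>`), with the planned counts as attribute `planned`.
#' @export
simulate_probe_targets <- function(probe, mismatch_counts, target_length = 300,
                                   seed = 1L, max_tries = 200L) {
  if (inherits(probe, "oligo_probe")) probe <- probe$seq
  probe <- toupper(probe)
  if (!grepl("^[ACGT]+$", probe)) {
    stop("generator probes must use the plain ACGT alphabet", call. = FALSE)
  }
  k <- nchar(probe)
  if (any(mismatch_counts < 0) || any(mismatch_counts != round(mismatch_counts))) {
    stop("mismatch counts must be non-negative integers", call. = FALSE)
  }
  if (any(mismatch_counts > k)) {
    stop("planned mismatch count exceeds the probe length", call. = FALSE)
  }
  if (target_length < k + 2) {
    stop("targets must be longer than the probe", call. = FALSE)
  }

  bases <- c("A", "C", "G", "T")
  site <- reverse_complement(probe)
  site_chars <- strsplit(site, "", fixed = TRUE)[[1]]

  with_seed(seed, {
    out <- character(length(mismatch_counts))
    for (j in seq_along(mismatch_counts)) {
      m <- mismatch_counts[j]
      done <- FALSE
      for (try in seq_len(max_tries)) {
        win <- site_chars
        if (m > 0) {
          pos <- sample.int(k, m)
          for (p in pos) win[p] <- sample(setdiff(bases, win[p]), 1L)
        }
        bg <- sample(bases, target_length, replace = TRUE)
        start <- sample.int(target_length - k + 1L, 1L)
        tgt <- bg
        tgt[start:(start + k - 1L)] <- win
        tgt <- paste(tgt, collapse = "")
        # verify: planted window is the unique global best at distance m
        scan <- min_mismatches(probe, tgt)
        if (scan$min_mismatches != m) next
        fwd <- window_mismatches(encode_seq(site), encode_seq(tgt))
        rev <- window_mismatches(encode_seq(site),
                                 encode_seq(reverse_complement(tgt)))
        if (sum(c(fwd, rev) == m) == 1L && fwd[start] == m) {
          out[j] <- tgt
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop(sprintf(
          "could not construct a unique-best target with %d mismatches", m),
          call. = FALSE)
      }
    }
    names(out) <- sprintf("planned_%d_%d", mismatch_counts,
                          seq_along(mismatch_counts))
    attr(out, "planned") <- mismatch_counts
    out
  })
}

#' Write target sequences to a FASTA file
#'
#' @param targets named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_targets_fasta <- function(targets, path) {
  x <- Biostrings::DNAStringSet(unclass(targets))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
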