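# Independent brute-force oracles, deliberately written with different
# mechanics than the package implementations they check.

# Plane accumulation by explicit per-pixel loop.
oracle_accumulate <- function(planes_list) {
  out <- matrix(0, nrow(planes_list[[1]]), ncol(planes_list[[1]]))
  for (r in seq_len(nrow(out))) {
    for (c in seq_len(ncol(out))) {
      s <- 0
      for (p in planes_list) if (!is.na(p[r, c])) s <- s + p[r, c]
      out[r, c] <- s
    }
  }
  out
}

# IUPAC base sets as character vectors (independent of the bitmask tables).
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", D = "H", H = "D",
            V = "B", N = "N")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# Minimal mismatch count by exhaustive window scan on both strands, using
# explicit set intersection per base.
oracle_min_mismatch <- function(probe, target) {
  site <- strsplit(oracle_revcomp(probe), "")[[1]]
  k <- length(site)
  best <- Inf
  for (tgt in c(toupper(target), oracle_revcomp(target))) {
    tc <- strsplit(tgt, "")[[1]]
    for (start in seq_len(length(tc) - k + 1)) {
      mm <- 0
      for (j in seq_len(k)) {
        if (length(intersect(ORACLE_SETS[[site[j]]],
                             ORACLE_SETS[[tc[start + j - 1]]])) == 0) {
          mm <- mm + 1
        }
      }
      best <- min(best, mm)
    }
  }
  best
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One-filament scene used across tests.
simple_filament_plan <- function(atom_fraction, density = 200, n_planes = 5,
                                 drift = NULL, seed = 1) {
  scene_plan(
    shape = c(48L, 48L), pixel_size_um = 0.5,
    objects = list(filament_object(c(4, 12), c(20, 12), width_um = 1.5,
                                   atom_fraction = atom_fraction,
                                   density = density)),
    n_planes = n_planes, drift = drift, seed = seed
  )
}
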