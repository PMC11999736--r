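# Shared fixtures, built in code.

# Four-catalyst example pool (amplitudes/rates of the worked multi-round
# example; background k = 0.001, Q = 0.2).
table1_species <- function() {
  tibble::tibble(
    label = paste0("seq", 1:4),
    A = c(0.55, 0.5, 0.7, 0.5),
    k = c(1.0, 0.8, 0.6, 0.5),
    p0 = 1e-14
  )
}

table1_pool <- function(artefact = NULL) {
  species_pool(table1_species(), Q = 0.2, kback = 0.001, artefact = artefact)
}

cofactor_example_pool <- function() {
  cofactor_pool(tibble::tibble(
    label = paste0("seq", 1:3),
    class = c("constitutive", "strict", "leaky"),
    A = 0.5, k = c(1, 0.8, 0.8), p0 = 1e-14
  ))
}

# Plain-R reference scanner: enumerate all module placements directly.
# Independent of the compiled code path; only usable on small inputs.
ref_min_distance <- function(sequence, struct) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  seq_chars[seq_chars == "T"] <- "U"
  Lran <- length(seq_chars)
  mods <- selexdyn:::structure_modules(struct)
  M <- nrow(mods)
  slack <- Lran - struct$Lstr
  canonical <- c("GC", "CG", "AU", "UA", "GU", "UG")
  mod_of <- function(p) findInterval(p, mods$start)
  shifts <- expand.grid(rep(list(0:slack), M))
  keep <- rep(TRUE, nrow(shifts))
  if (M > 1) {
    for (j in 2:M) keep <- keep & shifts[[j]] >= shifts[[j - 1]]
  }
  if (struct$anchored5) keep <- keep & shifts[[1]] == 0
  shifts <- shifts[keep, , drop = FALSE]
  best <- Inf
  cons_pos <- as.integer(names(struct$conserved))
  for (r in seq_len(nrow(shifts))) {
    sh <- as.integer(shifts[r, ])
    m <- 0
    for (i in seq_along(cons_pos)) {
      p <- cons_pos[i] + sh[mod_of(cons_pos[i])]
      if (seq_chars[p] != struct$conserved[[i]]) m <- m + 1
    }
    if (struct$b > 0) {
      for (i in seq_len(nrow(struct$pairs))) {
        a <- struct$pairs[i, 1] + sh[mod_of(struct$pairs[i, 1])]
        b <- struct$pairs[i, 2] + sh[mod_of(struct$pairs[i, 2])]
        if (!paste0(seq_chars[a], seq_chars[b]) %in% canonical) m <- m + 1
      }
    }
    if (m < best) best <- m
  }
  list(min_distance = best, n_placements = nrow(shifts))
}

random_rna <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}
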