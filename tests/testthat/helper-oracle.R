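# Independent oracles and fixture builders shared across tests.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA <- c("A", "C", "G", "T")

rand_seq <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

mutate_seq <- function(x, n_sub, alphabet = AA) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  paste(ch, collapse = "")
}

# identity oracle, independent of the package's DP: longest common
# subsequence via edit distance with substitutions costed as 2
lcs_identity <- function(a, b) {
  d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))
  lcs <- (nchar(a) + nchar(b) - as.numeric(d)) / 2
  lcs / min(nchar(a), nchar(b))
}

# plain-R reference implementation of the sorted-greedy clustering rule:
# sort length desc, count desc, lexicographic; join the earlier-founded
# representative of equal length with the highest identity >= threshold
naive_greedy <- function(peptides, counts, threshold) {
  ord <- order(-nchar(peptides), -counts, peptides, method = "radix")
  peptides <- peptides[ord]
  reps <- integer(0)
  assign <- integer(length(peptides))
  for (i in seq_along(peptides)) {
    best <- -1L
    best_id <- -1
    for (r in seq_along(reps)) {
      if (nchar(peptides[reps[r]]) != nchar(peptides[i])) next
      id <- lcs_identity(peptides[i], peptides[reps[r]])
      if (id >= threshold - 1e-9 && id > best_id + 1e-12) {
        best_id <- id
        best <- r - 1L
      }
    }
    if (best >= 0L) {
      assign[i] <- best
    } else {
      reps <- c(reps, i)
      assign[i] <- length(reps) - 1L
    }
  }
  split(peptides, assign)
}

# canonical form of a partition for comparison (order-free)
canon_partition <- function(groups) {
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = "|"),
                     character(1)),
              method = "radix"))
}

# lineage-structured peptide families: founders plus point-substitution
# variants, optionally on a shared framework so families sit near the given
# inter-family identity
make_families <- function(n_families, variants_each, len = 60,
                          max_sub = 3, shared_frac = 0) {
  framework <- sample(AA, len, replace = TRUE)
  var_pos <- sample(len, round((1 - shared_frac) * len))
  founders <- vapply(seq_len(n_families), function(i) {
    x <- framework
    x[var_pos] <- sample(AA, length(var_pos), replace = TRUE)
    paste(x, collapse = "")
  }, character(1))
  members <- lapply(founders, function(f) {
    unique(c(f, vapply(seq_len(variants_each - 1L), function(k)
      mutate_seq(f, sample(max_sub, 1)), character(1))))
  })
  list(founders = founders, members = members,
       peptides = unlist(members, use.names = FALSE),
       family = rep(seq_len(n_families), lengths(members)))
}

# error-free read pair covering an amplicon: forward mate from the 5' end,
# reverse mate the reverse complement of the 3' end
template_pair <- function(template, read_len) {
  rl <- min(read_len, nchar(template))
  list(fwd = substr(template, 1, rl),
       rev = revcomp(substr(template, nchar(template) - rl + 1, nchar(template))),
       qual = strrep("I", rl)) # Q40
}

# random in-frame amplicon: FR1 primer + interior codons + FR4 tail,
# avoiding stop codons
random_amplicon <- function(n_interior_codons = 106, fr4 = "T") {
  gc <- Biostrings::GENETIC_CODE
  ok <- names(gc)[gc != "*"]
  paste0("GAGGTGCAGCTGGTGGAGTCT",
         paste(sample(ok, n_interior_codons, replace = TRUE), collapse = ""),
         "ACCC", fr4, "GGTCACCGTCTCCTCA")
}
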