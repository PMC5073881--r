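# Independent brute-force oracles for the motif primitives. These scan
# character vectors position by position and share no code with the
# regex-based implementations they check.

AA20 <- setdiff(hrgpscan::AA_ALPHABET_X, "X")

rand_seq <- function(n, alphabet = AA20, weights = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = weights), collapse = "")
}

# Non-overlapping left-to-right literal motif count.
oracle_count_motif <- function(sequence, motif) {
  n <- nchar(sequence)
  m <- nchar(motif)
  count <- 0L
  i <- 1L
  while (i <= n - m + 1L) {
    if (substr(sequence, i, i + m - 1L) == motif) {
      count <- count + 1L
      i <- i + m
    } else {
      i <- i + 1L
    }
  }
  count
}

# Maximal S+P run tiers by character walk.
oracle_sp_tiers <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tiers <- c(sp3 = 0L, sp4 = 0L, sp5 = 0L)
  for (i in seq_len(n)) {
    if (chars[i] != "S") next
    k <- 0L
    j <- i + 1L
    while (j <= n && chars[j] == "P") {
      k <- k + 1L
      j <- j + 1L
    }
    if (k == 3L) tiers["sp3"] <- tiers["sp3"] + 1L
    if (k == 4L) tiers["sp4"] <- tiers["sp4"] + 1L
    if (k >= 5L) tiers["sp5"] <- tiers["sp5"] + 1L
  }
  tiers
}

oracle_dipeptide <- function(sequence, dipeptide) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  d <- strsplit(dipeptide, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(0L)
  sum(chars[1:(n - 1L)] == d[1L] & chars[2:n] == d[2L])
}

oracle_yxy <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 3L) return(0L)
  sum(chars[1:(n - 2L)] == "Y" & chars[3:n] == "Y" &
        chars[2:(n - 1L)] != "X")
}

oracle_ppvxkt <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  count <- 0L
  i <- 1L
  while (i <= n - 4L) {
    ok <- chars[i] == "P" && chars[i + 1L] == "P" && chars[i + 2L] == "V" &&
      chars[i + 3L] != "X" && chars[i + 4L] %in% c("K", "T")
    if (ok) {
      count <- count + 1L
      i <- i + 5L
    } else {
      i <- i + 1L
    }
  }
  count
}

# Recursive backtracking matcher for the fasciclin consensus with the
# same preference order as a greedy regex engine (longest repeat first),
# reporting leftmost non-overlapping matches.
FASC_ELEMS <- list(
  c("M", "A", "L", "I", "T"),
  "T",
  c("V", "I", "L", "S"),
  c("F", "L", "C", "M"),
  c("C", "A", "V", "T"),
  c("P", "V", "L", "I", "S"),
  list(set = strsplit("GSTKRNDPEIV", "")[[1L]]),
  c("D", "N", "S"),
  list(set = strsplit("DSENAGE", "")[[1L]]),
  c("A", "S", "Q", "M")
)

oracle_fasc_end <- function(chars, pos) {
  rec <- function(i, k) {
    if (k > length(FASC_ELEMS)) return(i)
    e <- FASC_ELEMS[[k]]
    if (is.list(e)) { # one-or-more, longest first
      run <- 0L
      j <- i
      while (j <= length(chars) && chars[j] %in% e$set) {
        j <- j + 1L
        run <- run + 1L
      }
      for (take in rev(seq_len(run))) {
        r <- rec(i + take, k + 1L)
        if (!is.na(r)) return(r)
      }
      return(NA_integer_)
    }
    if (i <= length(chars) && chars[i] %in% e) return(rec(i + 1L, k + 1L))
    NA_integer_
  }
  rec(pos, 1L)
}

oracle_fasciclin <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  spans <- NULL
  i <- 1L
  while (i <= length(chars)) {
    e <- oracle_fasc_end(chars, i)
    if (!is.na(e)) {
      spans <- rbind(spans, c(start = i - 1L, end = e - 1L))
      i <- e
    } else {
      i <- i + 1L
    }
  }
  if (is.null(spans)) {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  } else {
    spans
  }
}

# Random sequences for the fasciclin agreement property: half carry an
# embedded consensus instance (random class members, random repeat run
# lengths) mutated at 0-2 positions, so the set holds both true matches
# and near-miss negatives; the other half are plain random background.
rand_fasc_seq <- function() {
  bg1 <- rand_seq(sample(3:25, 1L))
  bg2 <- rand_seq(sample(3:25, 1L))
  if (stats::runif(1) < 0.5) return(paste0(bg1, bg2))
  inst <- c(
    sample(c("M", "A", "L", "I", "T"), 1L), "T",
    sample(c("V", "I", "L", "S"), 1L), sample(c("F", "L", "C", "M"), 1L),
    sample(c("C", "A", "V", "T"), 1L), sample(c("P", "V", "L", "I", "S"), 1L),
    sample(strsplit("GSTKRNDPEIV", "")[[1L]], sample(1:3, 1L),
           replace = TRUE),
    sample(c("D", "N", "S"), 1L),
    sample(strsplit("DSENAGE", "")[[1L]], sample(1:3, 1L), replace = TRUE),
    sample(c("A", "S", "Q", "M"), 1L))
  n_mut <- sample(0:2, 1L)
  if (n_mut > 0L) {
    at <- sample(seq_along(inst), n_mut)
    inst[at] <- sample(AA20, n_mut, replace = TRUE)
  }
  paste0(bg1, paste(inst, collapse = ""), bg2)
}

# A synth spec with nothing planted by default, for tests that need
# exact control over which classes are present.
spec0 <- function(..., seed = 1L) {
  zeros <- as.list(stats::setNames(
    rep(0L, 12L),
    c("classical_agp", "lysine_rich_agp", "ag_peptide", "fla",
      "classical_ext", "short_ext", "chimeric_ext", "prp",
      "pr_peptide_pplp", "pr_peptide_pelpk", "hybrid", "decoy")))
  args <- utils::modifyList(zeros, list(...))
  do.call(synth_spec, c(args, list(seed = seed)))
}
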