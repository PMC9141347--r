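# Independent oracles used by the property and acceptance tests. These
# deliberately re-derive results by brute force / enumeration and never
# call the code paths they check.

# exhaustive Smith-Waterman score (full matrix, score only)
sw_score_oracle <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  H <- matrix(0, length(a) + 1, length(b) + 1)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
    }
  }
  max(H)
}

# interval union length by position-set cardinality
union_len_oracle <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  length(unique(unlist(mapply(function(s, e) seq(s, e - 1L), starts, ends,
                              SIMPLIFY = FALSE))))
}

# six-frame ORF enumeration oracle: codon-table translation by lookup,
# independent index math
orf_oracle <- function(seq, min_aa) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- list()
  for (sgn in c(1L, -1L)) {
    s <- if (sgn > 0) seq else rc
    for (f in 1:3) {
      ncod <- (nchar(s) - f + 1L) %/% 3L
      if (ncod < 1L) next
      aa <- vapply(seq_len(ncod), function(k) {
        unname(code[substr(s, f + 3L * (k - 1L), f + 3L * k - 1L)])
      }, character(1))
      run_start <- NULL
      for (k in c(seq_len(ncod), ncod + 1L)) {
        if (k <= ncod && aa[k] != "*") {
          if (is.null(run_start)) run_start <- k
        } else {
          if (!is.null(run_start) && (k - run_start) >= min_aa) {
            nt0 <- (f - 1L) + 3L * (run_start - 1L)
            nt1 <- (f - 1L) + 3L * (k - 1L)
            if (sgn > 0) {
              out[[length(out) + 1L]] <- c(f, nt0, nt1)
            } else {
              out[[length(out) + 1L]] <- c(-f, n - nt1, n - nt0)
            }
          }
          run_start <- NULL
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(0), m_start = integer(0),
                      m_end = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("frame", "m_start", "m_end")
  df[order(df$frame, df$m_start), , drop = FALSE]
}

# brute-force gain/loss parsimony: enumerate every internal labeling,
# return min cost and the optimal event sets (edges named by child label)
parsimony_oracle <- function(tree, tip_states, gain_cost = 1, loss_cost = 1) {
  tips <- tree$labels[tree$is_tip]
  st <- as.integer(tip_states[tips])
  internal <- which(!tree$is_tip)
  k <- length(internal)
  stopifnot(k <= 14)
  best <- Inf
  opt <- list()
  for (mask in 0:(2^k - 1)) {
    lab <- integer(tree$n_nodes)
    lab[seq_len(tree$n_tips)] <- st
    lab[internal] <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
    par_state <- ifelse(is.na(tree$parent), 0L, lab[tree$parent])
    gains <- par_state == 0L & lab == 1L
    losses <- par_state == 1L & lab == 0L
    cost <- gain_cost * sum(gains) + loss_cost * sum(losses)
    if (cost < best) { best <- cost; opt <- list() }
    if (cost == best) {
      nm <- ifelse(is.na(tree$parent), "stem", tree$labels)
      key <- paste(paste(sort(nm[gains]), collapse = ","),
                   paste(sort(nm[losses]), collapse = ","), sep = "|")
      opt[[key]] <- list(gains = sort(nm[gains]), losses = sort(nm[losses]))
    }
  }
  list(cost = best, scenarios = opt[sort(names(opt))])
}

scenario_key <- function(s) {
  paste(paste(s$gains, collapse = ","), paste(s$losses, collapse = ","),
        sep = "|")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

fixture_tree <- function(name) {
  read_newick(system.file("extdata", paste0(name, "_tree.nwk"),
                          package = "tecurate"))
}

fixture_states <- function(name) {
  df <- utils::read.table(
    system.file("extdata", paste0(name, "_presence.tsv"),
                package = "tecurate"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(df$has_te, df$species)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
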