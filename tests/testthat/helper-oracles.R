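# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# --- sliding-window edit-distance unit scan -------------------------------
# Exhaustive detector: every start x window-width x strand combination is
# scored with utils::adist (Levenshtein with counts); acceptance uses the
# same contract as the detector (edit distance within budget), and the
# same greedy resolution (identity desc, start asc, "+" before "-").
oracle_find_units <- function(sequence, consensus = stcap_consensus(),
                              min_match_fraction = 0.90) {
  L <- nchar(consensus)
  min_matched <- min(floor(min_match_fraction * L) + 1L, L)
  budget <- L - min_matched
  n <- nchar(sequence)
  cand <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") consensus else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
    for (w in (L - budget):(L + budget)) {
      if (w > n) next
      starts <- 1:(n - w + 1L)
      wins <- substring(sequence, starts, starts + w - 1L)
      d <- utils::adist(pat, wins, counts = TRUE)
      cnt <- attr(d, "counts")
      ed <- as.integer(d[1, ])
      ok <- which(ed <= budget)
      if (!length(ok)) next
      ins <- cnt[1, ok, "ins"]; del <- cnt[1, ok, "del"]; sub <- cnt[1, ok, "sub"]
      matched <- L - sub - del
      keep <- matched >= min_matched
      ok <- ok[keep]
      if (!length(ok)) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = starts[ok] - 1L, end = starts[ok] - 1L + w, strand = strand,
        identity = matched[keep] / (L + ins[keep]),
        edits = ed[ok]
      )
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  cand <- do.call(rbind, cand)
  # for one (start, strand), keep only the best-identity window (then
  # fewest edits, then longest), mirroring one-hit-per-locus reporting
  cand <- cand[order(-cand$identity, cand$edits, -(cand$end - cand$start)), ]
  cand <- cand[!duplicated(cand[, c("start", "strand")]), ]
  cand <- cand[order(-cand$identity, cand$start, -(cand$end - cand$start), cand$strand), ]
  occupied <- logical(n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):cand$end[i]
    if (!any(occupied[span])) {
      keep[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  out <- cand[keep, c("start", "end", "strand")]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# --- silhouette, straight from the definition -----------------------------
oracle_silhouette <- function(cluster, d) {
  d <- as.matrix(d)
  n <- length(cluster)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cluster == cluster[i])
    a <- if (length(own) > 1L) mean(d[i, setdiff(own, i)]) else 0
    bs <- sapply(setdiff(unique(cluster), cluster[i]), function(k) {
      mean(d[i, cluster == k])
    })
    b <- min(bs)
    s[i] <- if (length(own) > 1L) (b - a) / max(a, b) else 0
  }
  s
}

# --- Robinson-Foulds by explicit bipartition enumeration ------------------
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) next
    tips <- tree$tip.label[unlist(phangorn::Descendants(tree, child, "tips"))]
    side <- sort(tips)
    other <- setdiff(labs, side)
    if (length(side) < 2L || length(other) < 2L) next # trivial split
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ",")) {
      paste(paste(side, collapse = ","), paste(other, collapse = ","), sep = "|")
    } else {
      paste(paste(other, collapse = ","), paste(side, collapse = ","), sep = "|")
    }
    out <- c(out, key)
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# --- exact 3-sequence sum-of-pairs alignment cost (unit costs) ------------
# cost: per pair, 1 per mismatch, 1 per base-vs-gap; gap-vs-gap is 0.
oracle_three_way_cost <- function(s1, s2, s3) {
  x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]; z <- strsplit(s3, "")[[1]]
  n1 <- length(x); n2 <- length(y); n3 <- length(z)
  INF <- 1e9
  D <- array(INF, dim = c(n1 + 1L, n2 + 1L, n3 + 1L))
  D[1, 1, 1] <- 0
  pcost <- function(a, b) {
    if (is.na(a) && is.na(b)) return(0)
    if (is.na(a) || is.na(b)) return(1)
    if (a == b) 0 else 1
  }
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    if (i + j + k == 0) next
    best <- INF
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      if (di + dj + dk == 0) next
      if (i - di < 0 || j - dj < 0 || k - dk < 0) next
      a <- if (di == 1) x[i] else NA
      b <- if (dj == 1) y[j] else NA
      c3 <- if (dk == 1) z[k] else NA
      step <- pcost(a, b) + pcost(a, c3) + pcost(b, c3)
      v <- D[i - di + 1L, j - dj + 1L, k - dk + 1L] + step
      if (v < best) best <- v
    }
    D[i + 1L, j + 1L, k + 1L] <- best
  }
  D[n1 + 1L, n2 + 1L, n3 + 1L]
}

# sum-of-pairs cost of a given MSA under the same unit costs
msa_sp_cost <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  cost <- 0
  for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
    a <- m[i, ]; b <- m[j, ]
    both <- a != "-" & b != "-"
    cost <- cost + sum(a[both] != b[both]) + sum(xor(a == "-", b == "-"))
  }
  cost
}

# --- misc fixtures ---------------------------------------------------------
mutate_seq <- function(x, rate) {
  ch <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# majority-overlap truth label for classified blocks
truth_block_labels <- function(blocks, truth_blocks) {
  lab <- integer(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    sel <- truth_blocks$arm == blocks$arm[i] &
      truth_blocks$start < blocks$end[i] & truth_blocks$end > blocks$start[i]
    if (!any(sel)) { lab[i] <- NA_integer_; next }
    ov <- pmin(truth_blocks$end[sel], blocks$end[i]) -
      pmax(truth_blocks$start[sel], blocks$start[i])
    lab[i] <- truth_blocks$type[sel][which.max(ov)]
  }
  lab
}

# clock species tree used for calibration tests (ages in MYA)
clock_species_tree <- function(rate = 0.05 / 19.5) {
  nwk <- paste0(
    "(((((((g1:2.5,g2:2.5):1.3,g3:3.8):1.2,g4:5.0):1.4,chimpanzee:6.4):2.2,",
    "human:8.6):6.6,orangutan:15.2):4.3,siamang:19.5);"
  )
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- tr$edge.length * rate
  list(tree = tr, rate = rate,
       calibrations = data.frame(
         tip_a = "g1",
         tip_b = c("chimpanzee", "human", "orangutan", "siamang"),
         age_mya = c(6.4, 8.6, 15.2, 19.5)
       ))
}

clade_key <- function(tree, node) {
  paste(sort(ape::extract.clade(tree, node)$tip.label), collapse = "|")
}

true_node_ages <- function(tree, rate) {
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  tip_depth <- max(depths[seq_len(n_tip)])
  ages <- c()
  for (nd in (n_tip + 1L):(n_tip + tree$Nnode)) {
    ages[clade_key(tree, nd)] <- (tip_depth - depths[nd]) / rate
  }
  ages
}
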