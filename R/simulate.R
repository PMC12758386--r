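#' Simulate a set of cap-bearing chromosome arms with ground truth
#'
#' Emits one sequence per arm, each a euchromatic flank followed by a
#' subterminal cap of alternating satellite arrays and SD-spacer copies,
#' with the telomere at the distal (right) end. Spacer copies are the
#' tree-root sequence evolved along the configured duplication tree by
#' per-site Poisson substitutions (no indels, so the true spacer MSA is
#' the identity). Satellite units within each array are drawn i.i.d. from
#' the array's block-type variant profile. Configured ectopic exchange
#' events are planted last via [plant_exchange()].
#'
#' The output is a deterministic function of the config (including its
#' seed): identical configs give byte-identical sequences and truth.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `cap_sim`: a list with `sequences`
#'   (named [Biostrings::DNAStringSet]), `truth` (list of BED-style
#'   data.frames: `units`, `arrays`, `spacers`, `blocks`, `caps`,
#'   `features`, `breakpoints`, plus `spacer_tree`) and `config`.
#' @export
simulate_cap_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cap_genome_impl(config))
}

simulate_cap_genome_impl <- function(config) {
  n_arms <- config$n_arms
  arm_names <- config$arm_names
  variant_seqs <- vapply(
    config$variants, function(s) apply_signature(config$unit_consensus, s),
    character(1)
  )
  variant_len <- nchar(variant_seqs)

  # arm structure draws
  n_arrays <- sample_range(config$arrays_per_cap[1], config$arrays_per_cap[2], n_arms)
  arm_arrays <- lapply(seq_len(n_arms), function(a) {
    m <- sample_range(config$units_per_array[1], config$units_per_array[2], n_arrays[a])
    t <- sample.int(nrow(config$type_profiles), n_arrays[a], replace = TRUE,
                    prob = config$arm_type_weights[a, ])
    list(n_units = m, type = t)
  })

  # spacer copies along the duplication tree
  n_slots <- sum(pmax(n_arrays - 1L, 0L))
  tree <- config$spacer_tree
  if (is.null(tree) && n_slots >= 2L) {
    tree <- ape::rcoal(n_slots, tip.label = sprintf("sp%02d", seq_len(n_slots)))
    depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_slots)])
    if (depth > 0) tree$edge.length <- tree$edge.length * (config$spacer_tree_depth / depth)
  }
  spacer_seqs <- character(0)
  if (n_slots > 0L) {
    root_seq <- random_dna(config$spacer_length)
    if (is.null(tree)) { # single slot, no tree needed
      spacer_seqs <- stats::setNames(root_seq, "sp01")
    } else {
      if (length(tree$tip.label) < n_slots) {
        stop("spacer_tree has fewer leaves than spacer slots (", n_slots, ")")
      }
      spacer_seqs <- evolve_tree_seqs(tree, root_seq)
    }
  }

  units <- list(); arrays <- list(); spacers <- list(); blocks <- list()
  caps <- list(); features <- list()
  seqs <- character(n_arms)
  slot <- 0L

  for (a in seq_len(n_arms)) {
    arm <- arm_names[a]
    flank <- random_dna(config$flank_length)
    features[[a]] <- simulate_boundary_features(arm, config)
    parts <- list(flank)
    pos <- config$flank_length # 0-based cursor
    cap_start <- pos
    st <- arm_arrays[[a]]
    for (i in seq_along(st$n_units)) {
      m <- st$n_units[i]
      ty <- st$type[i]
      vid <- sample.int(length(config$variants), m, replace = TRUE,
                        prob = config$type_profiles[ty, ])
      useqs <- variant_seqs[vid]
      ulen <- variant_len[vid]
      ustart <- pos + c(0L, cumsum(ulen[-m]))
      array_start <- pos
      array_end <- pos + sum(ulen)
      units[[length(units) + 1L]] <- data.frame(
        arm = arm, start = ustart, end = ustart + ulen, strand = "+",
        variant_id = vid, signature = unname(config$variants[vid])
      )
      arrays[[length(arrays) + 1L]] <- data.frame(
        arm = arm, start = array_start, end = array_end,
        n_units = m, type = ty
      )
      # truth blocks: tile the array at block_width (last tile partial)
      bs <- seq(array_start, array_end - 1L, by = config$block_width)
      blocks[[length(blocks) + 1L]] <- data.frame(
        arm = arm, start = bs, end = pmin(bs + config$block_width, array_end),
        type = ty
      )
      parts[[length(parts) + 1L]] <- paste(useqs, collapse = "")
      pos <- array_end
      if (i < length(st$n_units)) {
        slot <- slot + 1L
        leaf <- names(spacer_seqs)[slot]
        spacers[[length(spacers) + 1L]] <- data.frame(
          arm = arm, start = pos, end = pos + config$spacer_length,
          leaf = leaf
        )
        parts[[length(parts) + 1L]] <- unname(spacer_seqs[slot])
        pos <- pos + config$spacer_length
      }
    }
    caps[[a]] <- data.frame(arm = arm, start = cap_start, end = pos)
    seqs[a] <- paste(unlist(parts), collapse = "")
  }

  sim <- structure(
    list(
      sequences = Biostrings::DNAStringSet(stats::setNames(seqs, arm_names)),
      truth = list(
        units = do.call(rbind, units),
        arrays = do.call(rbind, arrays),
        spacers = if (length(spacers)) do.call(rbind, spacers) else
          data.frame(arm = character(), start = integer(), end = integer(), leaf = character()),
        blocks = do.call(rbind, blocks),
        caps = do.call(rbind, caps),
        features = do.call(rbind, features),
        breakpoints = data.frame(
          arm_a = character(), arm_b = character(),
          pos_a = integer(), pos_b = integer(), placement = character()
        ),
        spacer_tree = tree
      ),
      config = config
    ),
    class = "cap_sim"
  )
  for (ev in config$exchange_events) {
    sim <- plant_exchange(sim, ev)
  }
  sim
}

# Boundary-window feature placement: SD and gene intervals over the
# euchromatic flank, `fold` times denser inside the boundary window (the
# `width` bp adjacent to the cap) than elsewhere in the flank.
simulate_boundary_features <- function(arm, config) {
  b <- config$boundary
  win_start <- config$flank_length - b$width
  out <- list()
  for (cls in c("SD", "gene")) {
    per_kb <- if (cls == "SD") b$sd_per_kb else b$gene_per_kb
    lenr <- if (cls == "SD") b$sd_len else b$gene_len
    n_out <- stats::rpois(1, per_kb * win_start / 1000)
    n_in <- stats::rpois(1, per_kb * b$fold * b$width / 1000)
    if (n_out + n_in == 0L) next
    starts <- c(
      if (n_out > 0L) sample.int(win_start, n_out, replace = TRUE) - 1L,
      if (n_in > 0L) win_start + sample.int(b$width, n_in, replace = TRUE) - 1L
    )
    lens <- sample_range(lenr[1], lenr[2], n_out + n_in)
    ends <- pmin(starts + lens, config$flank_length)
    out[[cls]] <- data.frame(
      arm = arm, start = starts, end = ends, class = cls,
      in_boundary = starts >= win_start
    )
  }
  if (!length(out)) {
    return(data.frame(arm = character(), start = integer(), end = integer(),
                      class = character(), in_boundary = logical()))
  }
  do.call(rbind, out)
}

# Evolve a root sequence along a rooted tree: on each branch the number
# of substitution events is Poisson(branch length * L), each hitting a
# uniform site and replacing its base by one of the other three
# (Jukes-Cantor events; multiple hits allowed).
evolve_tree_seqs <- function(tree, root_seq) {
  L <- nchar(root_seq)
  n_tip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")
  seqs <- vector("list", n_tip + tree$Nnode)
  bases <- c("A", "C", "G", "T")
  seqs[[n_tip + 1L]] <- strsplit(root_seq, "")[[1]]
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    s <- seqs[[par]]
    nmut <- stats::rpois(1, tree$edge.length[i] * L)
    if (nmut > 0) {
      sites <- sample.int(L, nmut, replace = TRUE)
      for (k in sites) s[k] <- sample(bases[bases != s[k]], 1L)
    }
    seqs[[child]] <- s
  }
  out <- vapply(seqs[seq_len(n_tip)], paste, character(1), collapse = "")
  stats::setNames(out, tree$tip.label)
}

#' Plant an ectopic exchange between two arms
#'
#' Swaps the distal (telomere-side) segments of two arms beyond a
#' breakpoint on each, emulating an ectopic recombination event between
#' nonhomologous chromosomes, and remaps all ground-truth intervals
#' accordingly. With `placement = "in_spacer"` each breakpoint falls
#' strictly inside an SD-spacer interval; `"uniform"` places it anywhere
#' in the cap span. Explicit `pos_a`/`pos_b` override placement.
#'
#' Two event modes are supported. `mode = "swap"` (the default) is the
#' reciprocal exchange: both arms trade tails. `mode = "copy"` is
#' non-reciprocal: the recipient `arm_a` takes a copy of `arm_b`'s tail
#' while `arm_b` keeps its own — the configuration in which the event
#' remains visible as a near-identical nonallelic block pair, as it is
#' in real assemblies where the donor haplotype retains the original
#' sequence.
#'
#' @param sim A `cap_sim` object.
#' @param event List with `arm_a`, `arm_b`, optional `mode`
#'   (`"swap"`/`"copy"`) and either `placement`
#'   (`"in_spacer"`/`"uniform"`) or explicit breakpoints `pos_a`, `pos_b`.
#' @param seed Optional seed (the call inside [simulate_cap_genome()]
#'   already runs under the config seed).
#' @return The modified `cap_sim`; `truth$breakpoints` gains one row.
#' @export
plant_exchange <- function(sim, event, seed = NULL) {
  with_seed(seed, plant_exchange_impl(sim, event))
}

plant_exchange_impl <- function(sim, event) {
  tr <- sim$truth
  arm_a <- event$arm_a; arm_b <- event$arm_b
  stopifnot(arm_a %in% names(sim$sequences), arm_b %in% names(sim$sequences))
  placement <- event$placement %||% "in_spacer"
  pick <- function(arm) {
    cap <- tr$caps[tr$caps$arm == arm, ]
    if (placement == "in_spacer") {
      sp <- tr$spacers[tr$spacers$arm == arm, ]
      if (nrow(sp) == 0L) stop("no spacer on arm ", arm, " for in_spacer placement")
      sp <- sp[order(sp$start), , drop = FALSE]
      i <- if (!is.null(event$spacer_index)) {
        min(event$spacer_index, nrow(sp))
      } else {
        sample.int(nrow(sp), 1L)
      }
      sp$start[i] + sample.int(sp$end[i] - sp$start[i] - 1L, 1L)
    } else {
      cap$start + sample.int(cap$end - cap$start - 1L, 1L)
    }
  }
  pos_a <- event$pos_a %||% pick(arm_a)
  pos_b <- event$pos_b %||% pick(arm_b)
  cap_a <- tr$caps[tr$caps$arm == arm_a, ]
  cap_b <- tr$caps[tr$caps$arm == arm_b, ]
  if (pos_a < cap_a$start || pos_a >= cap_a$end) {
    stop("breakpoint ", pos_a, " outside cap span of ", arm_a)
  }
  if (pos_b < cap_b$start || pos_b >= cap_b$end) {
    stop("breakpoint ", pos_b, " outside cap span of ", arm_b)
  }

  mode <- event$mode %||% "swap"
  sa <- as.character(sim$sequences[[arm_a]])
  sb <- as.character(sim$sequences[[arm_b]])
  seqs <- as.character(sim$sequences)
  seqs[arm_a] <- paste0(substr(sa, 1L, pos_a), substr(sb, pos_b + 1L, nchar(sb)))
  if (mode == "swap") {
    seqs[arm_b] <- paste0(substr(sb, 1L, pos_b), substr(sa, pos_a + 1L, nchar(sa)))
  }
  sim$sequences <- Biostrings::DNAStringSet(seqs)

  for (nm in c("units", "arrays", "spacers", "blocks", "features")) {
    tr[[nm]] <- if (mode == "swap") {
      swap_truth_intervals(tr[[nm]], arm_a, arm_b, pos_a, pos_b)
    } else {
      copy_truth_intervals(tr[[nm]], arm_a, arm_b, pos_a, pos_b)
    }
  }
  # cap spans: recipient end moves; donor end moves only for a swap
  tr$caps$end[tr$caps$arm == arm_a] <- pos_a + (cap_b$end - pos_b)
  if (mode == "swap") {
    tr$caps$end[tr$caps$arm == arm_b] <- pos_b + (cap_a$end - pos_a)
  }
  tr$breakpoints <- rbind(tr$breakpoints, data.frame(
    arm_a = arm_a, arm_b = arm_b, pos_a = pos_a, pos_b = pos_b,
    placement = if (!is.null(event$pos_a)) "explicit" else placement
  ))
  sim$truth <- tr
  sim
}

# Remap truth rows for a non-reciprocal copy: the recipient arm_a loses
# everything beyond pos_a and gains shifted copies of arm_b's rows
# beyond pos_b; arm_b rows are untouched.
copy_truth_intervals <- function(df, arm_a, arm_b, pos_a, pos_b) {
  if (nrow(df) == 0L) return(df)
  shift <- pos_a - pos_b
  ra <- df[df$arm == arm_a, , drop = FALSE]
  keep_a <- ra[ra$start < pos_a, , drop = FALSE]
  keep_a$end <- pmin(keep_a$end, pos_a)
  rb <- df[df$arm == arm_b, , drop = FALSE]
  gain <- rb[rb$end > pos_b, , drop = FALSE]
  if (nrow(gain)) {
    gain$start <- pmax(gain$start, pos_b) + shift
    gain$end <- gain$end + shift
    gain$arm <- arm_a
  }
  rest <- df[df$arm != arm_a, , drop = FALSE]
  out <- rbind(rest, keep_a, gain)
  out <- out[order(out$arm, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Remap BED-style truth rows across a reciprocal distal swap. Rows fully
# beyond a breakpoint move to the partner arm (shifted); rows straddling
# a breakpoint are split.
swap_truth_intervals <- function(df, arm_a, arm_b, pos_a, pos_b) {
  if (nrow(df) == 0L) return(df)
  shift_ab <- pos_b - pos_a # moving a->b: + shift_ab
  move <- function(rows, from_pos, to_arm, shift) {
    keep <- list(); moved <- list()
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, , drop = FALSE]
      if (r$end <= from_pos) {
        keep[[length(keep) + 1L]] <- r
      } else if (r$start >= from_pos) {
        r$arm <- to_arm; r$start <- r$start + shift; r$end <- r$end + shift
        moved[[length(moved) + 1L]] <- r
      } else {
        r1 <- r; r1$end <- from_pos
        r2 <- r; r2$arm <- to_arm
        r2$start <- from_pos + shift; r2$end <- r$end + shift
        keep[[length(keep) + 1L]] <- r1
        moved[[length(moved) + 1L]] <- r2
      }
    }
    rbind(
      if (length(keep)) do.call(rbind, keep),
      if (length(moved)) do.call(rbind, moved)
    )
  }
  ra <- df[df$arm == arm_a, , drop = FALSE]
  rb <- df[df$arm == arm_b, , drop = FALSE]
  rest <- df[!(df$arm %in% c(arm_a, arm_b)), , drop = FALSE]
  out <- rbind(
    rest,
    move(ra, pos_a, arm_b, shift_ab),
    move(rb, pos_b, arm_a, -shift_ab)
  )
  out <- out[order(out$arm, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate bedMethyl-style CpG methylation calls
#'
#' For every CpG dinucleotide in the simulated arms, draws a per-site
#' methylation probability from a beta distribution whose mean depends on
#' the compartment (satellite array, SD spacer, or euchromatic flank) and
#' emits strand-specific modified/total read counts for both cytosines of
#' the CpG, so that strand merging is testable downstream. Satellite CpGs
#' are hypermethylated and spacer CpGs hypomethylated, mirroring the
#' pockets of reduced methylation observed at SD spacers in real caps.
#'
#' @param sim A `cap_sim` object.
#' @param seed Seed for the methylation draws; defaults to the config
#'   seed plus 101.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `n_mod`, `n_total` (one row per cytosine). The per-CpG ground truth
#'   (`chrom`, `start` of the C on the + strand, `p_true`, `class`) is
#'   attached as `attr(, "truth")`.
#' @export
simulate_methylation <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "cap_sim"))
  seed <- seed %||% (sim$config$seed + 101L)
  with_seed(seed, simulate_methylation_impl(sim))
}

simulate_methylation_impl <- function(sim) {
  m <- sim$config$meth
  calls <- list(); truth <- list()
  for (arm in names(sim$sequences)) {
    s <- as.character(sim$sequences[[arm]])
    cg <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (cg[1] == -1L) next
    pos0 <- as.integer(cg) - 1L # 0-based position of the + strand C
    cls <- classify_positions(pos0, sim$truth, arm)
    mean_of <- c(satellite = m$sat_mean, spacer = m$spacer_mean, flank = m$flank_mean)
    conc_of <- c(satellite = m$sat_conc, spacer = m$spacer_conc, flank = m$flank_conc)
    mu <- mean_of[cls]; cc <- conc_of[cls]
    p <- ifelse(is.finite(cc),
                stats::rbeta(length(pos0), mu * cc, (1 - mu) * cc),
                mu)
    # degenerate beta draws for mu in {0,1}
    p[mu == 0] <- 0; p[mu == 1] <- 1
    cov_p <- stats::rpois(length(pos0), m$coverage)
    cov_m <- stats::rpois(length(pos0), m$coverage)
    calls[[arm]] <- data.frame(
      chrom = arm,
      start = c(pos0, pos0 + 1L),
      end = c(pos0 + 1L, pos0 + 2L),
      strand = rep(c("+", "-"), each = length(pos0)),
      n_mod = c(stats::rbinom(length(pos0), cov_p, p),
                stats::rbinom(length(pos0), cov_m, p)),
      n_total = c(cov_p, cov_m)
    )
    truth[[arm]] <- data.frame(chrom = arm, start = pos0, p_true = unname(p),
                               class = unname(cls))
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), n_mod = integer(), n_total = integer())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- if (length(truth)) do.call(rbind, truth) else NULL
  out
}

# satellite / spacer / flank label for 0-based positions on one arm
classify_positions <- function(pos0, truth, arm) {
  cls <- rep("flank", length(pos0))
  ar <- truth$arrays[truth$arrays$arm == arm, ]
  sp <- truth$spacers[truth$spacers$arm == arm, ]
  in_any <- function(p, iv) {
    if (nrow(iv) == 0L) return(rep(FALSE, length(p)))
    ir <- bed_to_ir(iv$start, iv$end)
    IRanges::overlapsAny(IRanges::IRanges(p + 1L, p + 1L), ir)
  }
  cls[in_any(pos0, ar)] <- "satellite"
  cls[in_any(pos0, sp)] <- "spacer"
  cls
}

#' Write a simulated genome and its truth to disk
#'
#' FASTA for the arm sequences, BED for the truth interval sets, a
#' bedMethyl-like TSV if methylation calls are supplied, and a JSON
#' sidecar with the spacer tree (Newick) and the configuration scalars.
#'
#' @param sim A `cap_sim` object.
#' @param dir Output directory (created if missing).
#' @param methylation Optional output of [simulate_methylation()].
#' @return Invisibly, the vector of files written.
#' @export
write_cap_sim <- function(sim, dir, methylation = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fa <- file.path(dir, "arms.fasta")
  Biostrings::writeXStringSet(sim$sequences, fa)
  files <- c(files, fa)
  beds <- list(
    units = sim$truth$units[, c("arm", "start", "end", "signature")],
    arrays = sim$truth$arrays[, c("arm", "start", "end", "n_units")],
    spacers = sim$truth$spacers[, c("arm", "start", "end", "leaf")],
    blocks = sim$truth$blocks[, c("arm", "start", "end", "type")],
    caps = sim$truth$caps,
    features = sim$truth$features[, c("arm", "start", "end", "class")],
    breakpoints = sim$truth$breakpoints
  )
  for (nm in names(beds)) {
    f <- file.path(dir, paste0(nm, ".bed"))
    utils::write.table(beds[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(methylation)) {
    f <- file.path(dir, "methylation.tsv")
    utils::write.table(methylation, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    files <- c(files, f)
  }
  side <- list(
    seed = sim$config$seed,
    arm_names = sim$config$arm_names,
    consensus = sim$config$unit_consensus,
    variants = sim$config$variants,
    block_width = sim$config$block_width,
    spacer_length = sim$config$spacer_length,
    spacer_tree = if (!is.null(sim$truth$spacer_tree))
      ape::write.tree(sim$truth$spacer_tree) else NULL
  )
  f <- file.path(dir, "sim.json")
  jsonlite::write_json(side, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
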