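#' Structural-variant scan parameters
#'
#' @param min_sv_support Minimum clipped reads for a reportable breakpoint
#'   cluster (default 10).
#' @param cluster_window Clip positions within this many bp merge into one
#'   cluster (default 5).
#' @param transposase_read_threshold A sample's transposase evidence flag
#'   fires when strictly more than this many reads match the transposase
#'   database (default 20: 21 matching reads trigger, 20 do not).
#' @param identity_threshold Greedy clustering identity for the transposase
#'   database (default 0.95).
#' @param high_freq_threshold Inclusive high-frequency threshold on SV
#'   frequency (default 0.7).
#' @return A list of class `pula_sv_params`.
#' @export
sv_params <- function(min_sv_support = 10, cluster_window = 5,
                      transposase_read_threshold = 20,
                      identity_threshold = 0.95, high_freq_threshold = 0.7) {
  structure(list(min_sv_support = min_sv_support,
                 cluster_window = cluster_window,
                 transposase_read_threshold = transposase_read_threshold,
                 identity_threshold = identity_threshold,
                 high_freq_threshold = high_freq_threshold),
            class = "pula_sv_params")
}

#' Detect breakpoint clusters from soft-clipped reads
#'
#' Reads whose terminal soft clip reaches the aligner's
#' `min_softclip_report` contribute a clip event: left clips at the first
#' aligned base, right clips at the last. Events on the same side within
#' `cluster_window` bp merge; the cluster position is the modal clip point.
#' Clusters supported by at least `min_sv_support` clipped reads are
#' returned, together with the clipped tail sequences and the count of reads
#' that span the breakpoint cleanly (no nearby clip, at least
#' `min_softclip_report` aligned bp on both sides).
#'
#' @param aln `pula_alignments` from [align_reads()].
#' @param params [sv_params()].
#' @param aln_params [aligner_params()] (for the soft-clip threshold).
#' @return data.frame `pos`, `side` (`left-clip`/`right-clip`), `clip_reads`,
#'   `span_reads`, `frequency`, with a list-column `tails`.
#' @export
detect_breakpoints <- function(aln, params = sv_params(),
                               aln_params = aligner_params()) {
  m <- aln[aln$mapped, , drop = FALSE]
  empty <- data.frame(pos = integer(0), side = character(0),
                      clip_reads = integer(0), span_reads = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE)
  empty$tails <- list()
  if (!nrow(m)) return(empty)
  clips <- t(vapply(m$cigar, cigar_clips, c(left = 0L, right = 0L)))
  span <- vapply(m$cigar, cigar_ref_span, integer(1))
  ref_end <- m$ref_start + span - 1L
  len <- nchar(m$oriented_seq)
  thr <- aln_params$min_softclip_report
  sel_l <- which(clips[, "left"] >= thr)
  sel_r <- which(clips[, "right"] >= thr)
  ev <- rbind(
    data.frame(pos = m$ref_start[sel_l],
               side = rep("left-clip", length(sel_l)),
               tail = substr(m$oriented_seq, 1, clips[, "left"])[sel_l],
               stringsAsFactors = FALSE),
    data.frame(pos = ref_end[sel_r],
               side = rep("right-clip", length(sel_r)),
               tail = substr(m$oriented_seq, len - clips[, "right"] + 1,
                             len)[sel_r],
               stringsAsFactors = FALSE))
  if (!nrow(ev)) return(empty)
  out <- list()
  for (sd in c("left-clip", "right-clip")) {
    e <- ev[ev$side == sd, , drop = FALSE]
    if (!nrow(e)) next
    e <- e[order(e$pos), , drop = FALSE]
    brk <- c(0L, which(diff(e$pos) > params$cluster_window), nrow(e))
    for (g in seq_len(length(brk) - 1L)) {
      idx <- (brk[g] + 1L):brk[g + 1L]
      pos_tab <- table(e$pos[idx])
      modal <- as.integer(names(pos_tab)[which.max(pos_tab)])
      if (length(idx) < params$min_sv_support) next
      # spanning reads: cleanly aligned across the modal position
      covers <- m$ref_start + thr <= modal & ref_end - thr >= modal
      clip_near <- (clips[, "left"] >= thr &
                      abs(m$ref_start - modal) <= params$cluster_window) |
        (clips[, "right"] >= thr &
           abs(ref_end - modal) <= params$cluster_window)
      n_span <- sum(covers & !clip_near)
      row <- data.frame(pos = modal, side = sd,
                        clip_reads = length(idx), span_reads = n_span,
                        frequency = length(idx) / (length(idx) + n_span),
                        stringsAsFactors = FALSE)
      row$tails <- list(e$tail[idx])
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$pos, res$side), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Map clipped tails back onto the locus; returns the modal anchor position of
# mappable tails (ref_start for tails that extend rightwards, ref_end for
# leftwards) or NA when fewer than half of the tried tails map.
tail_locus_anchor <- function(tails, side, loc, aln_params, max_tails = 30) {
  tails <- tails[nchar(tails) >= 20]
  if (!length(tails)) return(NA_integer_)
  tails <- head(tails, max_tails)
  a <- align_reads(data.frame(id = paste0("t", seq_along(tails)), seq = tails,
                              stringsAsFactors = FALSE), loc, aln_params)
  a <- a[a$mapped & a$strand == "+", , drop = FALSE]
  if (nrow(a) < length(tails) / 2) return(NA_integer_)
  anchor <- if (side == "right-clip") a$ref_start else
    a$ref_start + vapply(a$cigar, cigar_ref_span, integer(1)) - 1L
  tab <- table(anchor)
  as.integer(names(tab)[which.max(tab)])
}

#' Call structural variants from breakpoint clusters
#'
#' Pairs clusters into typed events: a right-clip cluster whose tails re-map
#' to the locus downstream, matched with the corresponding left-clip cluster,
#' becomes a deletion spanning the gap (frequency averaged over both
#' breakpoints); adjacent right/left clusters whose tails do not re-map
#' locally become an insertion at that position. Unpaired clusters are
#' reported as `unresolved`. Frequencies are clipped/(clipped + spanning)
#' reads at the breakpoint; events at frequency >= `high_freq_threshold` are
#' flagged high-frequency.
#'
#' @param clusters From [detect_breakpoints()].
#' @param aln `pula_alignments` (unused by the pairing itself; kept for the
#'   module contract).
#' @param loc Reference [locus()].
#' @param params [sv_params()].
#' @param aln_params [aligner_params()].
#' @return data.frame `type` (`insertion`/`deletion`/`unresolved`), `start`,
#'   `end`, `support_reads`, `frequency`, `high_freq`, `element`,
#'   `element_reads`, with a list-column `tails`.
#' @export
call_structural_variants <- function(clusters, aln, loc,
                                     params = sv_params(),
                                     aln_params = aligner_params()) {
  empty <- data.frame(type = character(0), start = integer(0),
                      end = integer(0), support_reads = integer(0),
                      frequency = numeric(0), high_freq = logical(0),
                      element = character(0), element_reads = integer(0),
                      stringsAsFactors = FALSE)
  empty$tails <- list()
  if (!nrow(clusters)) return(empty)
  cw <- params$cluster_window
  anchors <- vapply(seq_len(nrow(clusters)), function(i) {
    tail_locus_anchor(clusters$tails[[i]], clusters$side[i], loc, aln_params)
  }, integer(1))
  used <- rep(FALSE, nrow(clusters))
  svs <- list()
  add_sv <- function(type, start, end, support, freq, tails) {
    row <- data.frame(type = type, start = start, end = end,
                      support_reads = support, frequency = freq,
                      high_freq = freq >= params$high_freq_threshold - 1e-12,
                      element = NA_character_, element_reads = NA_integer_,
                      stringsAsFactors = FALSE)
    row$tails <- list(tails)
    svs[[length(svs) + 1L]] <<- row
  }
  # deletions: right-clip at A with tails anchored at B, left-clip near B
  for (i in which(clusters$side == "right-clip")) {
    if (used[i] || is.na(anchors[i])) next
    A <- clusters$pos[i]; B <- anchors[i]
    if (B <= A + cw) next
    j <- which(!used & clusters$side == "left-clip" &
                 abs(clusters$pos - B) <= cw)
    if (!length(j)) next
    j <- j[1]
    used[c(i, j)] <- TRUE
    add_sv("deletion", A + 1L, B - 1L,
           clusters$clip_reads[i] + clusters$clip_reads[j],
           mean(c(clusters$frequency[i], clusters$frequency[j])),
           c(clusters$tails[[i]], clusters$tails[[j]]))
  }
  # insertions: adjacent right/left clusters with non-locus tails
  for (i in which(clusters$side == "right-clip")) {
    if (used[i] || !is.na(anchors[i])) next
    p <- clusters$pos[i]
    j <- which(!used & clusters$side == "left-clip" & is.na(anchors) &
                 abs(clusters$pos - (p + 1L)) <= cw)
    if (!length(j)) next
    j <- j[1]
    used[c(i, j)] <- TRUE
    clip <- clusters$clip_reads[i] + clusters$clip_reads[j]
    span <- clusters$span_reads[i] + clusters$span_reads[j]
    add_sv("insertion", p, p, clip, clip / (clip + span),
           c(clusters$tails[[i]], clusters$tails[[j]]))
  }
  for (i in which(!used)) {
    add_sv("unresolved", clusters$pos[i], clusters$pos[i],
           clusters$clip_reads[i], clusters$frequency[i],
           clusters$tails[[i]])
  }
  out <- do.call(rbind, svs)
  out <- out[order(out$start, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy identity clustering of a sequence set
#'
#' Builds a non-redundant representative set in the style of classic greedy
#' incremental clustering: sequences are sorted by decreasing length (ties
#' broken lexicographically by id), each is compared against existing
#' representatives in creation order, joins the first whose identity meets
#' the threshold, and otherwise founds a new cluster. Identity is defined on
#' a global alignment of the shorter sequence onto the longer (free end gaps
#' in the longer): matching columns / alignment columns.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param identity_threshold Minimum identity to join a cluster
#'   (default 0.95).
#' @param aln_params [aligner_params()] (alignment scores for the identity
#'   alignment).
#' @return A list of class `pula_transposase_db`: `representatives` (named
#'   character vector), `cluster_map` (data.frame `member`,
#'   `representative`, `identity`), `identity_threshold`.
#' @export
cluster_sequences <- function(seqs, identity_threshold = 0.95,
                              aln_params = aligner_params()) {
  db <- structure(list(representatives = character(0),
                       cluster_map = data.frame(member = character(0),
                                                representative = character(0),
                                                identity = numeric(0),
                                                stringsAsFactors = FALSE),
                       identity_threshold = identity_threshold),
                  class = "pula_transposase_db")
  if (!length(seqs)) return(db)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    joined <- FALSE
    for (rid in names(reps)) {
      r <- reps[[rid]]
      shorter <- if (nchar(s) <= nchar(r)) s else r
      longer <- if (nchar(s) <= nchar(r)) r else s
      fit <- fit_align_cpp(shorter, longer, aln_params$match,
                           aln_params$mismatch, aln_params$gap_open,
                           aln_params$gap_extend)
      if (fit$identity >= identity_threshold - 1e-12) {
        members[[length(members) + 1L]] <-
          data.frame(member = id, representative = rid,
                     identity = fit$identity, stringsAsFactors = FALSE)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps[id] <- s
      members[[length(members) + 1L]] <-
        data.frame(member = id, representative = id, identity = 1,
                   stringsAsFactors = FALSE)
    }
  }
  db$representatives <- reps
  db$cluster_map <- do.call(rbind, members)
  rownames(db$cluster_map) <- NULL
  db
}

#' Classify clipped tails and unmapped reads against the transposase database
#'
#' Each query (soft-clipped tail of reportable length, or fully unmapped
#' read) is aligned against every database representative with the same
#' local aligner and scoring as read mapping; it counts for its best-scoring
#' representative when the score reaches `min_report_score`. The sample's
#' transposase evidence flag fires when the total matching reads strictly
#' exceed `transposase_read_threshold`.
#'
#' @param tails Character vector of clipped tail sequences.
#' @param unmapped_seqs Character vector of unmapped read sequences.
#' @param db `pula_transposase_db` from [cluster_sequences()].
#' @param params [sv_params()].
#' @param aln_params [aligner_params()].
#' @return List with `counts` (named integer vector per representative,
#'   descending), `total`, `flag`.
#' @export
classify_clipped_reads <- function(tails, unmapped_seqs, db,
                                   params = sv_params(),
                                   aln_params = aligner_params()) {
  queries <- c(tails, unmapped_seqs)
  queries <- queries[nchar(queries) >= aln_params$min_softclip_report]
  if (!length(queries) || !length(db$representatives)) {
    return(list(counts = setNames(integer(0), character(0)), total = 0L,
                flag = FALSE))
  }
  scores <- matrix(0L, length(queries), length(db$representatives),
                   dimnames = list(NULL, names(db$representatives)))
  for (rid in names(db$representatives)) {
    res <- align_batch_cpp(queries, db$representatives[[rid]],
                           aln_params$seed_k, aln_params$match,
                           aln_params$mismatch, aln_params$gap_open,
                           aln_params$gap_extend, aln_params$band_width,
                           aln_params$min_report_score)
    scores[, rid] <- ifelse(res$mapped, res$score, 0L)
  }
  best <- apply(scores, 1, max)
  hit <- best >= aln_params$min_report_score
  best_rep <- colnames(scores)[apply(scores, 1, which.max)]
  tab <- table(factor(best_rep[hit], levels = names(db$representatives)))
  counts <- setNames(as.integer(tab), names(tab))
  counts <- counts[order(-counts, names(counts))]
  total <- sum(hit)
  list(counts = counts, total = as.integer(total),
       flag = total > params$transposase_read_threshold)
}

#' Attach transposase evidence to insertion structural variants
#'
#' Insertion SVs in a sample whose transposase classification flag fired are
#' annotated with the modal matching element and the sample's total matching
#' read count; deletions and unresolved events are never annotated.
#' Transposase read counts alone, without a supported SV, disrupt nothing.
#'
#' @param svs From [call_structural_variants()].
#' @param classification From [classify_clipped_reads()].
#' @return `svs` with `element` and `element_reads` populated where evidence
#'   applies.
#' @export
attach_transposase_evidence <- function(svs, classification) {
  if (!nrow(svs) || !isTRUE(classification$flag)) return(svs)
  ins <- which(svs$type == "insertion")
  if (length(ins) && length(classification$counts)) {
    svs$element[ins] <- names(classification$counts)[1]
    svs$element_reads[ins] <- classification$total
  }
  svs
}
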