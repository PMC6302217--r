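#' CRISPR detection parameters
#'
#' Defaults bracket the ~35 nt repeat / ~34 nt spacer geometry typical
#' of environmental arrays: repeats 21-48 nt, spacers 20-60 nt, at
#' least 3 repeat copies. `seed_k` is the exact-seed size of the
#' seed-and-extend detector; `min_identity` is the per-copy identity
#' required while chaining copies; `agreement` is the per-column
#' majority fraction used to refine repeat boundaries;
#' `periodic_score` is the windowed self-match fraction that calls a
#' candidate region in the periodicity detector.
#'
#' @param repeat_min,repeat_max direct-repeat length bounds (nt).
#' @param spacer_min,spacer_max spacer length bounds (nt).
#' @param min_copies minimum repeat copies per array.
#' @param seed_k exact k-mer seed size.
#' @param min_identity identity threshold for accepting a repeat copy.
#' @param agreement column-agreement threshold for boundary refinement.
#' @param periodic_window,periodic_score window size (nt) and score
#'   threshold of the periodicity detector.
#' @return a list of class `crispr_params`.
#' @export
crispr_params <- function(repeat_min = 21L, repeat_max = 48L,
                          spacer_min = 20L, spacer_max = 60L,
                          min_copies = 3L, seed_k = 8L,
                          min_identity = 0.7, agreement = 0.6,
                          periodic_window = 70L, periodic_score = 0.5) {
  p <- list(repeat_min = as.integer(repeat_min),
            repeat_max = as.integer(repeat_max),
            spacer_min = as.integer(spacer_min),
            spacer_max = as.integer(spacer_max),
            min_copies = as.integer(min_copies),
            seed_k = as.integer(seed_k),
            min_identity = min_identity, agreement = agreement,
            periodic_window = as.integer(periodic_window),
            periodic_score = periodic_score)
  if (p$repeat_min < p$seed_k) stop_field("repeat_min", "must be >= seed_k")
  if (p$repeat_max < p$repeat_min) stop_field("repeat_max", "must be >= repeat_min")
  if (p$spacer_max < p$spacer_min) stop_field("spacer_max", "must be >= spacer_min")
  if (p$min_copies < 2) stop_field("min_copies", "must be >= 2")
  structure(p, class = "crispr_params")
}

new_crispr_array <- function(contig_id, repeat_starts, repeat_length,
                             consensus, spacers, detector) {
  structure(list(
    contig_id = contig_id,
    start = repeat_starts[1],
    end = repeat_starts[length(repeat_starts)] + repeat_length,
    repeat_starts = as.integer(repeat_starts),
    repeat_length = as.integer(repeat_length),
    consensus_repeat = consensus,
    spacers = spacers,
    copies = length(repeat_starts),
    detector = detector
  ), class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array %s:%d-%d> %d copies of %d nt repeat (%s)\n",
              x$contig_id, x$start, x$end, x$copies, x$repeat_length,
              x$detector))
  invisible(x)
}

#' Check the structural invariants of a detected array
#'
#' Copies >= `min_copies`, one fewer spacer than copies, repeat and
#' spacer lengths inside the configured brackets, repeat starts
#' strictly increasing.
#'
#' @param array a `crispr_array`.
#' @param params a [crispr_params()].
#' @return `TRUE`, or a character vector of violated invariants.
#' @export
validate_crispr_array <- function(array, params = crispr_params()) {
  bad <- character(0)
  if (array$copies != length(array$repeat_starts)) {
    bad <- c(bad, "copies != |repeat_starts|")
  }
  if (array$copies < params$min_copies) bad <- c(bad, "copies < min_copies")
  if (length(array$spacers) != array$copies - 1L) {
    bad <- c(bad, "|spacers| != copies - 1")
  }
  if (array$repeat_length < params$repeat_min ||
      array$repeat_length > params$repeat_max) {
    bad <- c(bad, "repeat length out of range")
  }
  sl <- nchar(array$spacers)
  if (length(sl) > 0 && (any(sl < params$spacer_min) || any(sl > params$spacer_max))) {
    bad <- c(bad, "spacer length out of range")
  }
  if (is.unsorted(array$repeat_starts, strictly = TRUE)) {
    bad <- c(bad, "repeat starts not strictly increasing")
  }
  if (length(bad) == 0) TRUE else bad
}

# ---- shared low-level helpers -------------------------------------------

# identity between two equal-length character windows of `ch`
window_identity <- function(ch, i, j, len) {
  mean(ch[i:(i + len - 1L)] == ch[j:(j + len - 1L)])
}

# X-drop extension of an exact seed match at 1-based positions (a, b),
# both of length k. Score +1 match / -2 mismatch, stop when score falls
# `xdrop` below the running maximum; trim to the max-score point.
# Returns c(start_offset_left, end_offset_right) relative to the seed.
xdrop_extend <- function(ch, a, b, k, n, xdrop = 4L) {
  # right
  score <- 0; best <- 0; best_r <- 0L; r <- 0L
  while (TRUE) {
    pa <- a + k + r; pb <- b + k + r
    if (pb > n) break
    score <- score + if (ch[pa] == ch[pb]) 1 else -2
    r <- r + 1L
    if (score > best) { best <- score; best_r <- r }
    if (best - score >= xdrop) break
  }
  # left
  score <- 0; best <- 0; best_l <- 0L; l <- 0L
  while (TRUE) {
    pa <- a - 1L - l; pb <- b - 1L - l
    if (pa < 1L) break
    score <- score + if (ch[pa] == ch[pb]) 1 else -2
    l <- l + 1L
    if (score > best) { best <- score; best_l <- l }
    if (best - score >= xdrop) break
  }
  c(left = best_l, right = best_r)
}

# Gapless per-column majority consensus over repeat copies; ties broken
# by fixed base order A < C < G < T. Copies are cut at `starts` (1-based)
# with length `len`; out-of-range columns vote N (ignored).
column_profile <- function(ch, starts, len, n) {
  copies <- length(starts)
  prof <- matrix(0L, nrow = 4L, ncol = len,
                 dimnames = list(DNA_BASES, NULL))
  votes <- integer(len)
  for (s in starts) {
    idx <- s:(s + len - 1L)
    ok <- idx >= 1L & idx <= n
    bases <- ch[idx[ok]]
    cols <- which(ok)
    keep <- bases %in% DNA_BASES
    bases <- bases[keep]; cols <- cols[keep]
    for (j in seq_along(bases)) {
      prof[bases[j], cols[j]] <- prof[bases[j], cols[j]] + 1L
    }
    votes[cols] <- votes[cols] + 1L
  }
  list(profile = prof, votes = votes)
}

consensus_from_profile <- function(prof) {
  paste0(DNA_BASES[apply(prof, 2, which.max)], collapse = "")
}

# Gapless realignment of approximate copy starts: shift each start by
# the offset in [-slack, slack] that maximizes identity to a reference
# unit (first pass: the first copy; second pass: the majority
# consensus), removing the per-copy jitter of run-based copy calls.
realign_starts <- function(ch, n, starts, len, slack) {
  offsets <- -slack:slack
  # medoid reference: the copy most similar on average to all others;
  # robust to candidate starts that are spurious or badly offset
  ref <- starts[1]
  if (length(starts) > 2) {
    ok <- starts[starts >= 1L & starts + len - 1L <= n]
    if (length(ok) > 2) {
      sims <- vapply(ok, function(s) {
        mean(vapply(ok, function(t) window_identity(ch, s, t, len), 0))
      }, 0)
      ref <- ok[which.max(sims)]
    }
  }
  # pass 1: snap every start to the best offset against the reference
  starts <- vapply(starts, function(s) {
    cand <- s + offsets
    cand <- cand[cand >= 1L & cand + len - 1L <= n]
    if (length(cand) == 0) return(as.integer(s))
    ids <- vapply(cand, function(cs) window_identity(ch, ref, cs, len), 0)
    as.integer(cand[which.max(ids)])
  }, 0L)
  # pass 2: re-snap against the majority consensus of the aligned copies
  cp <- column_profile(ch, starts, len, n)
  cons <- seq_chars(consensus_from_profile(cp$profile))
  ref_fun <- function(cs) mean(ch[cs:(cs + len - 1L)] == cons)
  starts <- vapply(starts, function(s) {
    cand <- s + offsets
    cand <- cand[cand >= 1L & cand + len - 1L <= n]
    if (length(cand) == 0) return(as.integer(s))
    as.integer(cand[which.max(vapply(cand, ref_fun, 0))])
  }, 0L)
  sort(unique(starts))
}

# Refine repeat boundaries given approximate per-copy starts and length:
# realign copies to remove start jitter, widen each copy window by
# `slack`, keep the maximal run of columns whose majority-base
# agreement is >= params$agreement, and re-derive starts/length from
# that run. Returns NULL when refinement collapses below the length
# bracket.
refine_array <- function(ch, n, starts, len, params, slack = 8L) {
  # realignment slack covers run-start jitter from chance spacer
  # matches; 20 nt stays safely below the minimum array period, so a
  # copy can never snap onto its neighbour
  starts <- realign_starts(ch, n, starts, len, slack = 20L)
  wstarts <- starts - slack
  wlen <- len + 2L * slack
  cp <- column_profile(ch, wstarts, wlen, n)
  agree <- ifelse(cp$votes > 0, apply(cp$profile, 2, max) / cp$votes, 0)
  ok <- agree >= params$agreement
  if (!any(ok)) return(NULL)
  # maximal run of agreeing columns
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts_r <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c0 <- starts_r[best]; c1 <- ends[best]
  new_len <- c1 - c0 + 1L
  if (new_len < params$repeat_min || new_len > params$repeat_max) return(NULL)
  new_starts <- wstarts + c0 - 1L
  cp2 <- column_profile(ch, new_starts, new_len, n)
  consensus <- seq_chars(consensus_from_profile(cp2$profile))
  # drop candidate copies that do not resemble the consensus (spurious
  # flanking runs picked up by the region scan)
  ident <- vapply(new_starts, function(s) {
    idx <- s:(s + new_len - 1L)
    ok <- idx >= 1L & idx <= n
    if (!any(ok)) return(0)
    mean(ch[idx[ok]] == consensus[ok])
  }, 0)
  keep <- ident >= params$min_identity
  if (!any(keep)) return(NULL)
  new_starts <- new_starts[keep]
  # fill copies the run scan skipped: a gap of ~k periods is probed at
  # the interpolated lattice positions against the consensus
  if (length(new_starts) > 2) {
    period <- stats::median(diff(new_starts))
    probe <- function(s0) {
      cand <- (s0 - 8L):(s0 + 8L)
      cand <- cand[cand >= 1L & cand + new_len - 1L <= n]
      if (length(cand) == 0) return(NULL)
      ids <- vapply(cand, function(cs) {
        mean(ch[cs:(cs + new_len - 1L)] == consensus)
      }, 0)
      if (max(ids) >= params$min_identity) cand[which.max(ids)] else NULL
    }
    filled <- new_starts[1]
    for (i in 2:length(new_starts)) {
      gap <- new_starts[i] - new_starts[i - 1]
      k <- round(gap / period)
      if (k >= 2) {
        for (j in seq_len(k - 1)) {
          hit <- probe(new_starts[i - 1] + as.integer(round(j * gap / k)))
          if (!is.null(hit)) filled <- c(filled, hit)
        }
      }
      filled <- c(filled, new_starts[i])
    }
    new_starts <- sort(unique(filled))
  }
  cp3 <- column_profile(ch, new_starts, new_len, n)
  list(starts = new_starts, len = new_len,
       consensus = consensus_from_profile(cp3$profile))
}

# Drop leading/trailing copies whose identity to the consensus is poor,
# split the chain at spacer-length violations, and build array objects.
finalize_arrays <- function(ch, n, starts, len, consensus, params, detector,
                            contig_id, seqstr) {
  keep_segments <- list()
  # split where inter-start gap leaves a spacer outside the bracket
  seg <- c(starts[1])
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      gap <- starts[i] - (starts[i - 1] + len)
      if (gap >= params$spacer_min && gap <= params$spacer_max) {
        seg <- c(seg, starts[i])
      } else {
        keep_segments <- c(keep_segments, list(seg))
        seg <- c(starts[i])
      }
    }
  }
  keep_segments <- c(keep_segments, list(seg))
  out <- list()
  for (seg in keep_segments) {
    if (length(seg) < params$min_copies) next
    # recompute consensus over this segment only
    cp <- column_profile(ch, seg, len, n)
    cons <- consensus_from_profile(cp$profile)
    spacers <- vapply(seq_len(length(seg) - 1L), function(i) {
      substr(seqstr, seg[i] + len, seg[i + 1] - 1L)
    }, "")
    out <- c(out, list(new_crispr_array(
      contig_id = contig_id,
      repeat_starts = seg - 1L, # 0-based
      repeat_length = len, consensus = cons, spacers = spacers,
      detector = detector)))
  }
  out
}

# Low-complexity guard: a repeat unit matching itself at a small shift
# (homopolymer / short tandem) is not a CRISPR repeat.
is_low_complexity <- function(unit) {
  ch <- seq_chars(unit)
  L <- length(ch)
  for (shift in 1:min(5L, L - 1L)) {
    if (mean(ch[1:(L - shift)] == ch[(1 + shift):L]) >= 0.8) return(TRUE)
  }
  FALSE
}

# Merge overlapping detections of one locus, keeping the one with the
# most copies (ties: longest interval).
dedupe_arrays <- function(arrays) {
  if (length(arrays) <= 1) return(arrays)
  ord <- order(vapply(arrays, `[[`, 0L, "start"))
  arrays <- arrays[ord]
  kept <- list()
  for (a in arrays) {
    merged <- FALSE
    for (i in seq_along(kept)) {
      b <- kept[[i]]
      ov <- min(a$end, b$end) - max(a$start, b$start)
      if (ov > 0) {
        better <- a$copies > b$copies ||
          (a$copies == b$copies && (a$end - a$start) > (b$end - b$start))
        if (better) kept[[i]] <- a
        merged <- TRUE
        break
      }
    }
    if (!merged) kept <- c(kept, list(a))
  }
  kept
}

# ---- detector 1: seed-and-extend ----------------------------------------

#' Detect CRISPR arrays by seed-and-extend
#'
#' Indexes exact `seed_k`-mers, pairs occurrences recurring at offsets
#' compatible with one repeat + one spacer, extends each pair to a
#' maximal similar repeat unit (X-drop), then chains further copies in
#' both directions by best gapless identity within the spacer-length
#' window. Boundaries are refined by per-column majority agreement
#' across copies, and chains with at least `min_copies` copies are
#' emitted as arrays.
#'
#' @param x a [contig()] or sequence string.
#' @param params a [crispr_params()].
#' @return list of `crispr_array` (possibly empty).
#' @export
detect_arrays_seed <- function(x, params = crispr_params()) {
  seqstr <- as_sequence(x)
  contig_id <- if (inherits(x, "contig")) x$id else "seq1"
  n <- nchar(seqstr)
  k <- params$seed_k
  dmin <- params$repeat_min + params$spacer_min
  dmax <- params$repeat_max + params$spacer_max
  if (n < 2L * params$repeat_min + params$spacer_min) return(list())
  ch <- seq_chars(seqstr)
  # k-mer index (positions 1-based); skip k-mers containing N
  nk <- n - k + 1L
  kmers <- substring(seqstr, 1:nk, k:n)
  valid <- !grepl("N", kmers, fixed = TRUE)
  pos_by_kmer <- split(which(valid), kmers[valid])
  occ <- lengths(pos_by_kmer)
  # 2..100 occurrences: pairs below are never CRISPR seeds, far above is
  # low-complexity background that would swamp the anchor list
  pos_by_kmer <- pos_by_kmer[occ >= 2L & occ <= 100L]
  anchors <- vector("list", length(pos_by_kmer))
  for (pi in seq_along(pos_by_kmer)) {
    p <- pos_by_kmer[[pi]]
    m <- length(p)
    rows <- list()
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        d <- p[j] - p[i]
        if (d > dmax) break
        if (d >= dmin) rows[[length(rows) + 1L]] <- c(p[i], d)
      }
    }
    if (length(rows) > 0) anchors[[pi]] <- do.call(rbind, rows)
  }
  anchors <- anchors[!vapply(anchors, is.null, TRUE)]
  if (length(anchors) == 0) return(list())
  A <- do.call(rbind, anchors)
  A <- A[order(A[, 1]), , drop = FALSE]
  arrays <- list()
  covered <- function(pos) {
    any(vapply(arrays, function(a) pos >= a$start - 10 && pos <= a$end + 10,
               TRUE))
  }
  for (r in seq_len(nrow(A))) {
    a0 <- A[r, 1]; d <- A[r, 2]
    if (length(arrays) > 0 && covered(a0)) next
    ext <- xdrop_extend(ch, a0, a0 + d, k, n)
    len <- k + ext[["left"]] + ext[["right"]]
    if (len < params$repeat_min || len > params$repeat_max) next
    if (len > d) next # unit longer than the period: tandem, not CRISPR
    start1 <- a0 - ext[["left"]]
    unit <- substr(seqstr, start1, start1 + len - 1L)
    if (is_low_complexity(unit)) next
    chain <- chain_copies(ch, n, start1, d, len, params)
    if (length(chain) < params$min_copies) next
    ref <- refine_array(ch, n, chain, len, params)
    if (is.null(ref)) next
    found <- finalize_arrays(ch, n, ref$starts, ref$len, ref$consensus,
                             params, "seed", contig_id, seqstr)
    arrays <- c(arrays, found)
  }
  dedupe_arrays(arrays)
}

# Chain repeat copies in both directions from a unit at `start1` with
# initial period `d`. At each step the next copy start is chosen as the
# gapless-identity argmax over the spacer-compatible window; the chain
# stops when identity falls below params$min_identity.
chain_copies <- function(ch, n, start1, d, len, params) {
  probe <- function(ref_start, cand_starts) {
    cand_starts <- cand_starts[cand_starts >= 1L & cand_starts + len - 1L <= n]
    if (length(cand_starts) == 0) return(NULL)
    ids <- vapply(cand_starts, function(cs) {
      window_identity(ch, ref_start, cs, len)
    }, 0)
    best <- which.max(ids)
    if (ids[best] < params$min_identity) return(NULL)
    cand_starts[best]
  }
  starts <- c(start1, start1 + d)
  # right
  repeat {
    last <- starts[length(starts)]
    nxt <- probe(last, (last + len + params$spacer_min):(last + len + params$spacer_max))
    if (is.null(nxt)) break
    starts <- c(starts, nxt)
  }
  # left
  repeat {
    first <- starts[1]
    prv <- probe(first, (first - len - params$spacer_max):(first - len - params$spacer_min))
    if (is.null(prv)) break
    starts <- c(prv, starts)
  }
  starts
}

# ---- detector 2: periodic self-similarity -------------------------------

#' Detect CRISPR arrays by periodic self-similarity
#'
#' For every lag in the repeat+spacer period range, computes the
#' base-match indicator of the sequence against its own translate and
#' scores windowed match fractions; positions whose best-lag score
#' exceeds `periodic_score` seed candidate regions. Within each region
#' the matching runs at the best lag locate the repeat copies, and
#' boundaries are refined by per-copy column agreement. Degenerate
#' periodicity (homopolymers, short tandems) is suppressed by a
#' short-lag self-match filter.
#'
#' @inheritParams detect_arrays_seed
#' @return list of `crispr_array` (possibly empty).
#' @export
detect_arrays_periodic <- function(x, params = crispr_params()) {
  seqstr <- as_sequence(x)
  contig_id <- if (inherits(x, "contig")) x$id else "seq1"
  n <- nchar(seqstr)
  if (n < 2L * params$repeat_min + params$spacer_min) return(list())
  ch <- seq_chars(seqstr)
  w <- params$periodic_window
  dmin <- params$repeat_min + params$spacer_min
  dmax <- min(params$repeat_max + params$spacer_max, n - w)
  if (dmax < dmin) return(list())
  lags <- dmin:dmax
  best_score <- numeric(n); best_lag <- integer(n)
  match_by_lag <- vector("list", length(lags))
  for (li in seq_along(lags)) {
    lag <- lags[li]
    m <- ch[1:(n - lag)] == ch[(1 + lag):n]
    match_by_lag[[li]] <- m
    nm <- length(m)
    if (nm < w) next
    cs <- cumsum(m)
    win <- (cs[w:nm] - c(0, cs[1:(nm - w)])) / w
    idx <- 1:(nm - w + 1L)
    upd <- win > best_score[idx]
    if (any(upd)) {
      best_score[idx][upd] <- win[upd]
      best_lag[idx][upd] <- lag
    }
  }
  cand <- best_score >= params$periodic_score
  if (!any(cand)) return(list())
  # merge candidate positions into regions (gap tolerance one window)
  r <- rle(cand)
  ends <- cumsum(r$lengths); starts_r <- ends - r$lengths + 1L
  regions <- cbind(starts_r[r$values], ends[r$values])
  if (nrow(regions) > 1) {
    merged <- regions[1, , drop = FALSE]
    for (i in 2:nrow(regions)) {
      if (regions[i, 1] - merged[nrow(merged), 2] <= w) {
        merged[nrow(merged), 2] <- regions[i, 2]
      } else merged <- rbind(merged, regions[i, ])
    }
    regions <- merged
  }
  arrays <- list()
  for (ri in seq_len(nrow(regions))) {
    r0 <- regions[ri, 1]; r1 <- regions[ri, 2] + w - 1L
    span <- r0:min(r1, n)
    lag <- as.integer(stats::median(best_lag[span][best_lag[span] > 0]))
    if (is.na(lag) || lag < dmin) next
    # complexity filter: strong self-match at short lags => tandem repeat
    short_ok <- TRUE
    for (sl in 1:min(12L, dmin - 1L)) {
      hi <- min(r1, n - sl)
      if (hi <= r0) next
      if (mean(ch[r0:hi] == ch[(r0 + sl):(hi + sl)]) >= 0.6) {
        short_ok <- FALSE; break
      }
    }
    if (!short_ok) next
    li <- match(lag, lags)
    m <- match_by_lag[[li]]
    lo <- max(1L, r0 - lag); hi <- min(length(m), r1)
    seg <- m[lo:hi]
    # close gaps of up to 2 mismatches inside runs
    segc <- close_gaps(seg, 2L)
    rr <- rle(segc)
    rends <- cumsum(rr$lengths); rstarts <- rends - rr$lengths + 1L
    good <- which(rr$values & rr$lengths >= floor(0.8 * params$repeat_min))
    if (length(good) == 0) next
    run_starts <- lo + rstarts[good] - 1L
    run_lens <- rr$lengths[good]
    len0 <- as.integer(round(stats::median(run_lens)))
    len0 <- min(max(len0, params$repeat_min), params$repeat_max)
    starts <- c(run_starts, run_starts[length(run_starts)] + lag)
    if (length(starts) < params$min_copies) next
    ref <- refine_array(ch, n, starts, len0, params)
    if (is.null(ref)) next
    found <- finalize_arrays(ch, n, ref$starts, ref$len, ref$consensus,
                             params, "periodic", contig_id, seqstr)
    arrays <- c(arrays, found)
  }
  dedupe_arrays(arrays)
}

# Close FALSE gaps of length <= `tol` between TRUE runs.
close_gaps <- function(x, tol) {
  r <- rle(x)
  if (length(r$lengths) > 2) {
    inner <- 2:(length(r$lengths) - 1L)
    flip <- inner[!r$values[inner] & r$lengths[inner] <= tol]
    r$values[flip] <- TRUE
  }
  inverse.rle(r)
}
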