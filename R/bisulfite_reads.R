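# Bisulfite amplicon read simulation and per-CpG methylation calling.
#
# The quantification chain is: assign paired-end reads to panel markers
# by exhaustive end-anchored alignment against the (<= 16) converted
# references, count C/T per interrogated offset (overlapping mate bases
# counted once, first mate wins), estimate the conversion rate from the
# pooled non-CpG cytosine controls, correct the raw beta for conversion
# failure, and flag offsets below the minimum coverage (default 1000
# reads, the depth floor set for reliable quantification).
#
# Amplicon reads carry no indels at this scale (indel-aware realignment
# is out of scope), so semi-global alignment reduces to ungapped scoring
# at the two amplicon ends, in both orientations, with reference CpG and
# control positions matching C and T at zero cost. Identical reads are
# collapsed before scoring; results are identical to per-read scoring.

#' Simulate paired-end bisulfite amplicon reads
#'
#' For each marker, `n_fragments` bisulfite-converted template molecules
#' are drawn: each CpG offset is methylated independently with
#' probability `true_beta` (methylated C stays C; unmethylated C
#' converts to T with probability `conversion_rate`), every control
#' cytosine converts with probability `conversion_rate`, and uniform
#' substitution errors are applied at `seq_error_rate`. Read 1 is the
#' first `read_len` bases of the fragment; read 2 the reverse complement
#' of the last `read_len` bases (both truncated to the amplicon length).
#'
#' @param panel a `marker_panel`.
#' @param true_betas named numeric vector, one true methylation fraction
#'   per marker cpg_id (applied to all CpG offsets of that amplicon).
#' @param n_fragments fragments per marker.
#' @param conversion_rate bisulfite conversion probability in (0.5, 1\].
#' @param seq_error_rate per-base substitution error probability.
#' @param read_len read length in bp (150 for a 300-cycle paired run).
#' @param seed integer seed.
#' @return object of class `read_batch`: a `data.frame` with columns
#'   `read_id`, `mate`, `sequence`, `quality` and (for evaluation only;
#'   the quantifier never reads it) `true_marker`.
#' @export
simulate_reads <- function(panel, true_betas, n_fragments = 1000L,
                           conversion_rate = 1.0, seq_error_rate = 0,
                           read_len = 150L, seed = 1L) {
  stopifnot(inherits(panel, "marker_panel"))
  if (conversion_rate <= 0.5 || conversion_rate > 1)
    stop("conversion_rate must be in (0.5, 1]")
  missing <- setdiff(names(panel), names(true_betas))
  if (length(missing))
    stop("true_betas missing markers: ", paste(missing, collapse = ", "))
  with_seed(seed, {
    parts <- lapply(names(panel), function(id) {
      amp <- panel[[id]]
      simulate_marker_reads(amp, true_betas[[id]], n_fragments,
                            conversion_rate, seq_error_rate, read_len)
    })
    out <- do.call(rbind, parts)
    class(out) <- c("read_batch", "data.frame")
    out
  })
}

simulate_marker_reads <- function(amp, beta, n, conversion_rate,
                                  seq_error_rate, read_len) {
  L <- amp$length
  ref <- strsplit(amp$reference_seq, "")[[1L]]
  var_pos <- sort(c(amp$cpg_offsets, amp$control_offsets)) + 1L
  is_cpg <- var_pos %in% (amp$cpg_offsets + 1L)
  k <- length(var_pos)
  # per-fragment base at each variable position
  bases <- matrix("T", n, k)
  for (j in seq_len(k)) {
    if (is_cpg[j]) {
      meth <- stats::runif(n) < beta
      conv <- stats::runif(n) < conversion_rate
      bases[, j] <- ifelse(meth, "C", ifelse(conv, "T", "C"))
    } else {
      bases[, j] <- ifelse(stats::runif(n) < conversion_rate, "T", "C")
    }
  }
  # collapse identical variable-position patterns; fragments are the
  # reference with those bases substituted
  key <- apply(bases, 1L, paste, collapse = "")
  uk <- unique(key)
  idx <- match(key, uk)
  frags_u <- vapply(uk, function(pat) {
    ch <- ref
    ch[var_pos] <- strsplit(pat, "")[[1L]]
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
  l1 <- min(read_len, L)
  r1 <- substr(frags_u, 1L, l1)[idx]
  r2 <- revcomp(substr(frags_u, L - l1 + 1L, L))[idx]
  if (seq_error_rate > 0) {
    r1 <- add_substitution_errors(r1, seq_error_rate)
    r2 <- add_substitution_errors(r2, seq_error_rate)
  }
  ids <- sprintf("%s_f%06d", amp$cpg_id, seq_len(n))
  data.frame(
    read_id = rep(ids, 2L), mate = rep(c(1L, 2L), each = n),
    sequence = c(r1, r2), quality = strrep("I", l1),
    true_marker = amp$cpg_id, stringsAsFactors = FALSE)
}

add_substitution_errors <- function(seqs, rate) {
  l <- nchar(seqs[1L])
  n_err <- stats::rbinom(length(seqs), l, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(l, n_err[i])
    ch <- strsplit(seqs[i], "")[[1L]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Write / read a paired-end read batch as FASTQ
#'
#' @param batch a `read_batch`.
#' @param r1_path,r2_path FASTQ files for mates 1 and 2.
#' @return `write_fastq` returns the paths invisibly; `read_fastq` a
#'   `read_batch` (without truth labels).
#' @export
write_fastq <- function(batch, r1_path, r2_path) {
  for (m in 1:2) {
    sub <- batch[batch$mate == m, ]
    seqs <- Biostrings::DNAStringSet(sub$sequence)
    names(seqs) <- sub$read_id
    q <- Biostrings::PhredQuality(
      vapply(nchar(sub$sequence), strrep, "", x = "I"))
    qs <- Biostrings::QualityScaledDNAStringSet(seqs, q)
    Biostrings::writeQualityScaledXStringSet(
      qs, if (m == 1L) r1_path else r2_path)
  }
  invisible(c(r1_path, r2_path))
}

#' @rdname write_fastq
#' @export
read_fastq <- function(r1_path, r2_path = NULL) {
  load1 <- function(path, mate) {
    s <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    data.frame(read_id = sub("\\s.*$", "", names(s)), mate = mate,
               sequence = as.character(s),
               quality = as.character(S4Vectors::mcols(s)$qualities),
               stringsAsFactors = FALSE)
  }
  out <- load1(r1_path, 1L)
  if (!is.null(r2_path)) out <- rbind(out, load1(r2_path, 2L))
  rownames(out) <- NULL
  class(out) <- c("read_batch", "data.frame")
  out
}

# ungapped identity of unique reads against one reference chunk;
# amb marks positions where C and T both match at zero cost
score_block <- function(readmat, refch, amb) {
  hits <- readmat == matrix(refch, nrow(readmat), length(refch),
                            byrow = TRUE)
  if (any(amb)) {
    ambm <- matrix(amb, nrow(readmat), length(refch), byrow = TRUE)
    hits <- hits | (ambm & (readmat == "C" | readmat == "T"))
  }
  rowSums(hits)
}

#' Assign reads to panel markers
#'
#' Every read is scored against every marker reference by ungapped
#' alignment anchored at either amplicon end, in both orientations, with
#' reference CpG/control positions matching C and T at zero cost. A read
#' is assigned to the best-scoring marker; reads whose best identity
#' falls below `min_identity`, or that tie across distinct markers, go
#' to the unassigned bin. An empty batch yields an empty result.
#'
#' @param batch a `read_batch`.
#' @param panel a `marker_panel`.
#' @param min_identity minimum fraction of matching bases.
#' @return `data.frame`: `read_id`, `mate`, `marker` (`NA` when
#'   unassigned), `tmpl_seq` (read oriented to the reference strand),
#'   `tmpl_start` (1-based start on the reference), `identity`.
#' @export
assign_reads <- function(batch, panel, min_identity = 0.8) {
  stopifnot(inherits(panel, "marker_panel"))
  empty <- data.frame(read_id = character(0), mate = integer(0),
                      marker = character(0), tmpl_seq = character(0),
                      tmpl_start = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(batch)) return(empty)
  refs <- lapply(panel, function(amp) {
    ch <- strsplit(amp$reference_seq, "")[[1L]]
    amb <- logical(length(ch))
    amb[c(amp$cpg_offsets, amp$control_offsets) + 1L] <- TRUE
    amb <- amb | ch == "Y"
    list(ch = ch, amb = amb, L = amp$length)
  })
  res <- data.frame(read_id = batch$read_id, mate = batch$mate,
                    marker = NA_character_,
                    tmpl_seq = NA_character_, tmpl_start = NA_integer_,
                    identity = NA_real_, stringsAsFactors = FALSE)
  for (l in unique(nchar(batch$sequence))) {
    sel <- which(nchar(batch$sequence) == l)
    seqs <- batch$sequence[sel]
    useq <- unique(seqs)
    uidx <- match(seqs, useq)
    urc <- revcomp(useq)
    m_fwd <- matrix(unlist(strsplit(useq, ""), use.names = FALSE),
                    length(useq), l, byrow = TRUE)
    m_rev <- matrix(unlist(strsplit(urc, ""), use.names = FALSE),
                    length(useq), l, byrow = TRUE)
    best <- matrix(-1L, length(useq), 2L)  # score, second-best score
    best_marker <- rep(NA_character_, length(useq))
    best_start <- rep(NA_integer_, length(useq))
    best_orient <- rep(NA_character_, length(useq))
    best_len <- rep(l, length(useq))
    for (mk in names(refs)) {
      rf <- refs[[mk]]
      ll <- min(l, rf$L)
      anchors <- unique(c(1L, rf$L - ll + 1L))
      for (orient in c("fwd", "rev")) {
        mm <- if (orient == "fwd") m_fwd else m_rev
        # runoff reads longer than the reference: score the overlapping
        # prefix (fwd anchor) / suffix (end anchor)
        for (a in anchors) {
          rpos <- a:(a + ll - 1L)
          cpos <- if (a == 1L) 1:ll else (l - ll + 1L):l
          sc <- score_block(mm[, cpos, drop = FALSE], rf$ch[rpos],
                            rf$amb[rpos])
          improve <- sc > best[, 1L]
          tie <- sc == best[, 1L] & best_marker != mk &
            !is.na(best_marker)
          best[tie, 2L] <- sc[tie]
          best[improve, 2L] <- best[improve, 1L]
          best[improve, 1L] <- sc[improve]
          best_marker[improve] <- mk
      best_start[improve] <- a
          best_orient[improve] <- orient
          best_len[improve] <- ll
        }
      }
    }
    identity <- best[, 1L] / best_len
    unassigned <- identity < min_identity | best[, 1L] == best[, 2L]
    tmpl <- ifelse(best_orient == "rev", urc, useq)
    res$marker[sel] <- ifelse(unassigned, NA_character_,
                              best_marker)[uidx]
    res$tmpl_seq[sel] <- tmpl[uidx]
    res$tmpl_start[sel] <- best_start[uidx]
    res$identity[sel] <- identity[uidx]
  }
  res
}

#' Call per-CpG methylation for one marker
#'
#' Counts C and T (other bases and N go to `other_count`) at every
#' interrogated offset of the amplicon from the reads assigned to it.
#' Where mates overlap, the base is counted once (first mate wins). The
#' conversion rate is estimated from the pooled control offsets, raw
#' betas are conversion-corrected, and coverage is flagged against
#' `min_reads`.
#'
#' @param assignments output of [assign_reads()] (any markers; rows for
#'   other markers are ignored).
#' @param amp the [amplicon()] to call.
#' @param min_reads minimum C+T coverage for `pass_coverage`.
#' @return `data.frame` (one row per offset): `marker`, `offset`, `type`
#'   (`target`/`cpg`/`control`), `genomic_position` (target row only),
#'   `c_count`, `t_count`, `other_count`, `coverage`, `raw_beta`,
#'   `conversion_rate`, `corrected_beta`, `pass_coverage`.
#' @export
call_methylation <- function(assignments, amp, min_reads = 1000L) {
  rows <- assignments[!is.na(assignments$marker) &
                        assignments$marker == amp$cpg_id, , drop = FALSE]
  offsets <- sort(c(amp$cpg_offsets, amp$control_offsets))
  type <- ifelse(offsets %in% amp$control_offsets, "control",
                 ifelse(offsets == amp$target_cpg_offset, "target", "cpg"))
  out <- data.frame(
    marker = amp$cpg_id, offset = offsets, type = type,
    genomic_position = ifelse(type == "target", amp$position, NA_integer_),
    c_count = 0, t_count = 0, other_count = 0, stringsAsFactors = FALSE)
  if (nrow(rows)) {
    m1 <- rows[rows$mate == 1L, ]
    m2 <- rows[rows$mate == 2L, ]
    pair <- merge(
      data.frame(read_id = m1$read_id, seq1 = m1$tmpl_seq,
                 start1 = m1$tmpl_start, stringsAsFactors = FALSE),
      data.frame(read_id = m2$read_id, seq2 = m2$tmpl_seq,
                 start2 = m2$tmpl_start, stringsAsFactors = FALSE),
      by = "read_id", all = TRUE)
    # collapse identical (seq1, seq2) pairs; counts are weighted
    key <- paste(pair$seq1, pair$start1, pair$seq2, pair$start2)
    uk <- !duplicated(key)
    w <- as.vector(table(factor(key, levels = key[uk])))
    up <- pair[uk, , drop = FALSE]
    for (i in seq_along(offsets)) {
      pos <- offsets[i] + 1L
      p1 <- pos - up$start1 + 1L
      in1 <- !is.na(up$start1) & p1 >= 1L & p1 <= nchar(up$seq1)
      p2 <- pos - up$start2 + 1L
      in2 <- !is.na(up$start2) & p2 >= 1L & p2 <= nchar(up$seq2)
      base <- rep(NA_character_, nrow(up))
      use2 <- in2 & !in1          # first mate wins in the overlap
      base[use2] <- substr(up$seq2[use2], p2[use2], p2[use2])
      base[in1] <- substr(up$seq1[in1], p1[in1], p1[in1])
      out$c_count[i] <- sum(w[!is.na(base) & base == "C"])
      out$t_count[i] <- sum(w[!is.na(base) & base == "T"])
      out$other_count[i] <- sum(w[!is.na(base) & base != "C" &
                                    base != "T"])
    }
  }
  out$coverage <- out$c_count + out$t_count
  out$raw_beta <- ifelse(out$coverage > 0, out$c_count / out$coverage,
                         NA_real_)
  ctrl <- out[out$type == "control", ]
  rate <- if (sum(ctrl$c_count + ctrl$t_count) == 0) NA_real_
          else conversion_rate(ctrl)
  out$conversion_rate <- rate
  out$corrected_beta <- if (is.na(rate)) NA_real_ else
    ifelse(is.na(out$raw_beta), NA_real_,
           correct_conversion(out$raw_beta, rate))
  out$pass_coverage <- out$coverage >= min_reads
  out
}

#' Conversion rate from control-offset counts
#'
#' Pooled over a marker's non-CpG cytosine controls:
#' `rate = total T / (total C + total T)`. Every control cytosine should
#' read T after complete conversion, so residual C measures conversion
#' failure.
#'
#' @param control_rows callset rows at control offsets (needs `c_count`
#'   and `t_count`).
#' @return conversion rate in \[0, 1\].
#' @export
conversion_rate <- function(control_rows) {
  cc <- sum(control_rows$c_count); tt <- sum(control_rows$t_count)
  if (cc + tt == 0) stop("no conversion controls observed")
  tt / (cc + tt)
}

#' Correct a raw beta for incomplete bisulfite conversion
#'
#' Inverts the conversion process: an unmethylated cytosine reads C with
#' probability (1 − rate), so `raw = beta + (1 − beta)(1 − rate)` and
#' `corrected = (raw − (1 − rate)) / rate`, clamped to \[0, 1\].
#' `rate = 1` is the identity.
#'
#' @param raw_beta observed C fraction(s).
#' @param rate conversion rate; rates at or below 0.5 indicate assay
#'   failure and are refused.
#' @return corrected beta value(s) in \[0, 1\].
#' @export
correct_conversion <- function(raw_beta, rate) {
  if (rate <= 0.5)
    stop("conversion rate ", signif(rate, 3),
         " <= 0.5: assay failure, refusing to correct")
  clamp01((raw_beta - (1 - rate)) / rate)
}

#' Quantify a read batch against a panel
#'
#' Convenience wrapper: [assign_reads()] then [call_methylation()] for
#' every marker.
#'
#' @param batch a `read_batch` (or FASTQ paths via [read_fastq()]).
#' @param panel a `marker_panel`.
#' @param min_reads coverage threshold.
#' @param min_identity assignment identity threshold.
#' @return object of class `methylation_callset`: the row-bound per-
#'   marker call tables; attribute `unassigned_n` counts unassigned
#'   reads.
#' @export
quantify_reads <- function(batch, panel, min_reads = 1000L,
                           min_identity = 0.8) {
  asg <- assign_reads(batch, panel, min_identity = min_identity)
  calls <- do.call(rbind, lapply(panel, call_methylation,
                                 assignments = asg,
                                 min_reads = min_reads))
  rownames(calls) <- NULL
  attr(calls, "unassigned_n") <- sum(is.na(asg$marker))
  class(calls) <- c("methylation_callset", "data.frame")
  calls
}

#' Extract the per-marker target betas from a callset
#'
#' @param calls a `methylation_callset`.
#' @param require_coverage refuse markers failing the coverage filter
#'   (`NA` instead when `FALSE`).
#' @return named numeric vector of corrected target betas, one per
#'   marker.
#' @export
target_betas <- function(calls, require_coverage = TRUE) {
  tg <- calls[calls$type == "target", ]
  b <- tg$corrected_beta
  if (require_coverage) b[!tg$pass_coverage] <- NA_real_
  stats::setNames(b, tg$marker)
}

#' Average corrected betas across replicate callsets
#'
#' Replicate measurements (e.g. triplicate sequencing runs of one
#' sample) are averaged per marker after coverage filtering; replicates
#' failing coverage for a marker are dropped with a warning, and markers
#' with no passing replicate are `NA`.
#'
#' @param callsets list of `methylation_callset`s of the same panel.
#' @return named numeric vector of averaged corrected target betas.
#' @export
average_replicates <- function(callsets) {
  p <- sum(callsets[[1L]]$type == "target")
  mats <- matrix(unlist(lapply(callsets, target_betas,
                               require_coverage = FALSE)), nrow = p,
                 dimnames = list(
                   callsets[[1L]]$marker[callsets[[1L]]$type == "target"],
                   NULL))
  pass <- matrix(unlist(lapply(callsets, function(cs)
    cs$pass_coverage[cs$type == "target"])), nrow = p)
  mats[!pass] <- NA_real_
  n_fail <- sum(!pass)
  if (n_fail > 0)
    warning(n_fail, " marker replicate(s) failed coverage; ",
            "averaging over passing replicates")
  out <- rowMeans(mats, na.rm = TRUE)
  out[rowSums(pass) == 0L] <- NA_real_
  out
}
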