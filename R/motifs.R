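#' IUPAC nucleotide code utilities
#'
#' `iupac_bases()` expands a single IUPAC code to the concrete bases it
#' denotes; `reverse_complement()` reverse-complements a DNA (or IUPAC
#' consensus) string vector.
#'
#' @param code single IUPAC character.
#' @return for `iupac_bases`, a string of concrete bases.
#' @export
iupac_bases <- function(code) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
           B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  out <- map[toupper(code)]
  if (any(is.na(out))) stop("not an IUPAC code: ", code[is.na(out)][1])
  unname(out)
}

#' @rdname iupac_bases
#' @param x character vector of DNA/IUPAC strings.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""),
         character(1))
}

#' Define a consensus motif pattern
#'
#' @param name motif name used in hit tables.
#' @param consensus IUPAC consensus string (length >= 4).
#' @param both_strands scan the reverse complement as well?
#' @return object of class `motif_pattern`.
#' @export
motif_pattern <- function(name, consensus, both_strands = TRUE) {
  consensus <- toupper(consensus)
  if (nchar(consensus) < 4) stop("consensus must be at least 4 bases")
  chars <- strsplit(consensus, "")[[1]]
  ok <- chars %in% c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N")
  if (!all(ok)) stop("invalid IUPAC code in consensus: ", chars[!ok][1])
  structure(list(name = name, consensus = consensus,
                 both_strands = both_strands),
            class = "motif_pattern")
}

# IUPAC consensus -> regex character classes. A pattern N matches subject N
# (and any base); every other code matches only its concrete bases, so an N
# in the subject never satisfies a non-N code.
iupac_regex <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  cls <- vapply(chars, function(cd) {
    b <- iupac_bases(cd)
    if (cd == "N") b <- paste0(b, "N")
    if (nchar(b) == 1) b else paste0("[", b, "]")
  }, character(1))
  paste(cls, collapse = "")
}

check_sequence <- function(sequence) {
  bad <- regexpr("[^ACGTN]", toupper(sequence))
  if (bad > 0)
    stop("invalid character in sequence at position ", bad,
         " (0-based ", bad - 1L, ")")
  invisible(TRUE)
}

# all 0-based start positions of a regex, overlapping matches included
regex_starts <- function(sequence, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Finds every position (overlaps included) where the consensus matches on
#' the forward strand and, when enabled, where the reverse complement of
#' the window matches (reported on the minus strand at forward
#' coordinates). A palindromic match at one position is collapsed to a
#' single plus-strand hit.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param pattern a [motif_pattern()] or a bare IUPAC consensus string.
#' @param both_strands overrides the pattern's flag when not `NULL`.
#' @return data frame: motif, start (0-based), strand, match (the forward
#'   substring at the hit).
#' @export
scan_iupac <- function(sequence, pattern, both_strands = NULL) {
  if (!inherits(pattern, "motif_pattern"))
    pattern <- motif_pattern(pattern, pattern)
  if (is.null(both_strands)) both_strands <- pattern$both_strands
  sequence <- toupper(sequence)
  check_sequence(sequence)
  w <- nchar(pattern$consensus)
  fwd <- regex_starts(sequence, iupac_regex(pattern$consensus))
  hits <- data.frame(motif = character(0), start = integer(0),
                     strand = character(0), match = character(0),
                     stringsAsFactors = FALSE)
  if (length(fwd))
    hits <- data.frame(motif = pattern$name, start = fwd, strand = "+",
                       match = substring(sequence, fwd + 1L, fwd + w),
                       stringsAsFactors = FALSE)
  if (both_strands) {
    rc_pat <- reverse_complement(pattern$consensus)
    rev <- regex_starts(sequence, iupac_regex(rc_pat))
    rev <- setdiff(rev, fwd)  # palindromic double counts collapse to '+'
    if (length(rev))
      hits <- rbind(hits, data.frame(
        motif = pattern$name, start = rev, strand = "-",
        match = substring(sequence, rev + 1L, rev + w),
        stringsAsFactors = FALSE))
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

# run a per-strand pair grammar on one strand of a sequence; used by the
# composite scanner. Returns forward-coordinate left/right starts + spacer.
pair_hits_one_strand <- function(sequence, left_rx, right_rx, wl, wr,
                                 spacer_min, spacer_max) {
  ls <- regex_starts(sequence, left_rx)
  rs <- regex_starts(sequence, right_rx)
  if (!length(ls) || !length(rs))
    return(data.frame(start_left = integer(0), start_right = integer(0),
                      spacer = integer(0)))
  grid <- expand.grid(start_left = ls, start_right = rs)
  spacer <- grid$start_right - (grid$start_left + wl)
  keep <- spacer >= spacer_min & spacer <= spacer_max
  data.frame(start_left = grid$start_left[keep],
             start_right = grid$start_right[keep],
             spacer = as.integer(spacer[keep]))
}

#' Scan for composite two-element motifs separated by a spacer
#'
#' Reports every pair of a left element (default E-box, CANNTG) and a right
#' element (default WGATAR) on the same strand with the left element 5' of
#' the right element on that strand and a gap of `spacer_min` to
#' `spacer_max` bases (inclusive) strictly between the two footprints.
#' Overlapping composites are all reported.
#'
#' @param sequence DNA string.
#' @param left,right IUPAC consensus strings of the two elements.
#' @param spacer_min,spacer_max inclusive spacer bounds (bp between the
#'   element footprints).
#' @param both_strands scan the minus strand as well (coordinates reported
#'   on the forward strand)?
#' @return data frame: start_left, start_right (0-based forward
#'   coordinates of each element's footprint), strand, spacer.
#' @export
scan_composite <- function(sequence, left = "CANNTG", right = "WGATAR",
                           spacer_min = 6, spacer_max = 14,
                           both_strands = TRUE) {
  stopifnot(spacer_min >= 0, spacer_min <= spacer_max)
  sequence <- toupper(sequence)
  check_sequence(sequence)
  wl <- nchar(left); wr <- nchar(right)
  lrx <- iupac_regex(left); rrx <- iupac_regex(right)
  plus <- pair_hits_one_strand(sequence, lrx, rrx, wl, wr,
                               spacer_min, spacer_max)
  plus$strand <- rep("+", nrow(plus))
  out <- plus
  if (both_strands) {
    L <- nchar(sequence)
    rc <- reverse_complement(sequence)
    minus <- pair_hits_one_strand(rc, lrx, rrx, wl, wr,
                                  spacer_min, spacer_max)
    if (nrow(minus)) {
      # map reverse-complement coordinates back to forward coordinates
      sl <- L - (minus$start_left + wl)
      sr <- L - (minus$start_right + wr)
      minus <- data.frame(start_left = sl, start_right = sr,
                          spacer = minus$spacer,
                          strand = "-", stringsAsFactors = FALSE)
      out <- rbind(out, minus)
    }
  }
  out[order(out$start_left, out$start_right), , drop = FALSE]
}

#' Scan for tandem double motifs
#'
#' Reports pairs of occurrences of one consensus (default WGATAR) whose
#' footprints do not overlap and are separated by at most `spacer_max`
#' bases. Hits on both strands are considered; the `orientation` argument
#' restricts which strand combinations count (`"same"` = both hits on one
#' strand, `"convergent"` = upstream hit on plus and downstream on minus,
#' `"divergent"` the reverse, `"any"` = no restriction).
#'
#' @param sequence DNA string.
#' @param pattern IUPAC consensus (default "WGATAR").
#' @param spacer_max maximum gap (bp) between the two footprints.
#' @param orientation character vector of allowed strand combinations.
#' @return data frame: start_first, start_second (forward 0-based, ordered
#'   by coordinate), strand_first, strand_second, spacer.
#' @export
scan_double <- function(sequence, pattern = "WGATAR", spacer_max = 5,
                        orientation = c("same", "convergent")) {
  stopifnot(spacer_max >= 0)
  hits <- scan_iupac(sequence, motif_pattern("tandem", pattern,
                                             both_strands = TRUE))
  empty <- data.frame(start_first = integer(0), start_second = integer(0),
                      strand_first = character(0),
                      strand_second = character(0), spacer = integer(0))
  if (nrow(hits) < 2) return(empty)
  w <- nchar(pattern)
  hits <- hits[order(hits$start), ]
  n <- nrow(hits)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i < pairs$j, ]
  spacer <- hits$start[pairs$j] - (hits$start[pairs$i] + w)
  keep <- spacer >= 0 & spacer <= spacer_max
  pairs <- pairs[keep, ]; spacer <- spacer[keep]
  if (!nrow(pairs)) return(empty)
  s1 <- hits$strand[pairs$i]; s2 <- hits$strand[pairs$j]
  combo <- ifelse(s1 == s2, "same",
                  ifelse(s1 == "+" & s2 == "-", "convergent", "divergent"))
  ok <- if ("any" %in% orientation) rep(TRUE, length(combo))
        else combo %in% orientation
  data.frame(start_first = hits$start[pairs$i][ok],
             start_second = hits$start[pairs$j][ok],
             strand_first = s1[ok], strand_second = s2[ok],
             spacer = as.integer(spacer[ok]), stringsAsFactors = FALSE)
}

# count hits of one pattern spec in one sequence; spec is either an IUPAC
# string / motif_pattern, or list(type = "composite"/"double", ...)
count_motif_hits <- function(sequence, spec) {
  if (is.list(spec) && !inherits(spec, "motif_pattern")) {
    if (identical(spec$type, "composite")) {
      return(nrow(scan_composite(
        sequence,
        left = spec$left %||% "CANNTG", right = spec$right %||% "WGATAR",
        spacer_min = spec$spacer_min %||% 6,
        spacer_max = spec$spacer_max %||% 14)))
    }
    if (identical(spec$type, "double")) {
      return(nrow(scan_double(
        sequence, pattern = spec$pattern %||% "WGATAR",
        spacer_max = spec$spacer_max %||% 5)))
    }
    stop("unknown motif spec type")
  }
  nrow(scan_iupac(sequence, spec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Motif statistics across peak classes
#'
#' For every peak class (a named list of sequence sets) and every pattern,
#' computes the fraction of peaks carrying at least one hit and the hit
#' density per kb, then compares classes pairwise with a two-proportion
#' test (fraction of peaks with a hit) and a Mann-Whitney rank test on
#' per-peak hit counts.
#'
#' @param seq_sets named list of named character vectors (sequences by
#'   peak class).
#' @param patterns named list; each element an IUPAC consensus string, a
#'   [motif_pattern()], or a list with `type = "composite"`/`"double"` and
#'   the corresponding scanner arguments.
#' @return list with `fractions` (data frame class x motif: n, n_with_hit,
#'   fraction, hits_per_kb) and `tests` (pairwise enrichment statistics).
#' @export
peak_set_motif_stats <- function(seq_sets, patterns = list(
                                   GATA = "WGATAR", EBOX = "CANNTG",
                                   composite = list(type = "composite"),
                                   double_GATA = list(type = "double"))) {
  stopifnot(length(seq_sets) >= 1, all(lengths(seq_sets) >= 1))
  classes <- names(seq_sets)
  counts <- lapply(seq_sets, function(seqs) {
    sapply(names(patterns), function(pn) {
      vapply(seqs, count_motif_hits, numeric(1), spec = patterns[[pn]])
    }, simplify = FALSE)
  })
  frac <- do.call(rbind, lapply(classes, function(cl) {
    do.call(rbind, lapply(names(patterns), function(pn) {
      x <- counts[[cl]][[pn]]
      kb <- sum(nchar(seq_sets[[cl]])) / 1000
      data.frame(class = cl, motif = pn, n = length(x),
                 n_with_hit = sum(x > 0),
                 fraction = mean(x > 0),
                 hits_per_kb = sum(x) / kb,
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- list()
  if (length(classes) >= 2) {
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(names(patterns), function(pn) {
        xa <- counts[[pr[1]]][[pn]]; xb <- counts[[pr[2]]][[pn]]
        pt <- proportion_test(sum(xa > 0), length(xa),
                              sum(xb > 0), length(xb))
        rt <- rank_tests(xa, xb, kind = "mann_whitney_two_sample")
        data.frame(class_a = pr[1], class_b = pr[2], motif = pn,
                   prop_p = pt$p.value, rank_p = rt$p.value,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  list(fractions = frac, tests = tests)
}
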