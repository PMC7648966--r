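# Cross-study junction-set comparison on a shared coordinate frame.
# Matching is exact-coordinate by default; inputs must already share one
# assembly (no coordinate lifting here). An optional slack window allows
# +/- N nt fuzzy matching for cross-pipeline comparison.

#' Canonical junction keys of a record table
#'
#' @param table data.frame with `chrom`, `start`, `end` (and `strand` when
#'   `strand_aware`).
#' @param strand_aware include the strand in the key (default `TRUE`).
#' @return deduplicated character vector of keys.
#' @export
canonical_key <- function(table, strand_aware = TRUE) {
  unique(junction_key(table, strand_aware))
}

#' Membership-region counts of 2-5 junction sets
#'
#' Counts every membership region of the venn partition (2^n - 1 regions),
#' plus per-set totals and the union size. With `slack > 0`, keys whose
#' start and end each differ by at most `slack` nt (same chromosome and,
#' when applicable, strand) are matched; each element is assigned the
#' membership of every set containing a match.
#'
#' @param sets named list of key vectors (from [canonical_key()]) or of
#'   data.frames accepted by it.
#' @param strand_aware passed to [canonical_key()] for data.frame inputs.
#' @param slack fuzzy-match window in nt (default 0 = exact).
#' @return list with `regions` (data.frame: membership pattern, member set
#'   names, count), `totals` (per-set sizes) and `union`.
#' @export
overlap_sets <- function(sets, strand_aware = TRUE, slack = 0L) {
  if (length(sets) < 2L || length(sets) > 5L)
    stopf("overlap_sets accepts 2-5 sets (got %d)", length(sets))
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- sprintf("set%d", seq_along(sets))
  keys <- lapply(sets, function(s) {
    if (is.data.frame(s)) canonical_key(s, strand_aware) else unique(s)
  })
  universe <- unique(unlist(keys, use.names = FALSE))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(keys)))
  if (slack > 0L) {
    parse <- function(k) {
      p <- strsplit(k, ":", fixed = TRUE)
      data.frame(chrom = vapply(p, `[`, character(1), 1L),
                 start = as.integer(vapply(p, `[`, character(1), 2L)),
                 end = as.integer(vapply(p, `[`, character(1), 3L)),
                 strand = vapply(p, function(x)
                   if (length(x) >= 4L) x[4L] else "*", character(1)),
                 stringsAsFactors = FALSE)
    }
    uni <- parse(universe)
    for (si in seq_along(keys)) {
      kt <- parse(keys[[si]])
      for (i in which(!member[, si])) {
        hit <- kt$chrom == uni$chrom[i] &
          abs(kt$start - uni$start[i]) <= slack &
          abs(kt$end - uni$end[i]) <= slack &
          (kt$strand == uni$strand[i])
        if (any(hit)) member[i, si] <- TRUE
      }
    }
  }
  n <- length(keys)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1L, , drop = FALSE]
  regions <- do.call(rbind, lapply(seq_len(nrow(patterns)), function(pi) {
    pat <- as.logical(patterns[pi, ])
    cnt <- sum(apply(member, 1L, function(r) identical(unname(r), pat)))
    data.frame(pattern = paste(as.integer(pat), collapse = ""),
               members = paste(names(keys)[pat], collapse = "&"),
               count = cnt, stringsAsFactors = FALSE)
  }))
  list(regions = regions,
       totals = vapply(keys, length, integer(1)),
       union = length(universe))
}
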