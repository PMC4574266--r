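## Triple pattern search.
##
## Each index holds a permutation of triple rows sorted by (bin key, sort
## keys). Indices are rebuilt lazily: insertion just invalidates them, and
## the first query after a batch of insertions pays one O(n log n) sort.
## Query planning: among indices whose bin key is constrained by the
## pattern, pick the one whose sort order covers the most additionally
## constrained keys as a prefix (ties broken by index declaration order);
## with no usable index, fall back to a linear scan.
##
## When a counter environment is supplied, element comparisons are counted:
## one per binary-search probe, and one per candidate row per constrained
## key tested during residual filtering / scanning (short-circuit order).

.tripCol <- function(e, key) {
  switch(key, s = e$ts, p = e$tp, o = e$to, d = e$td)
}

.ensureIndex <- function(e, i) {
  ix <- e$idx[[i]]
  n <- e$nt
  if (ix$built == n) return(ix)
  cols <- lapply(c(ix$bin, ix$sort), function(k) .tripCol(e, k)[seq_len(n)])
  ix$ord <- do.call(order, c(cols, list(method = "radix")))
  ix$built <- n
  e$idx[[i]] <- ix
  ix
}

.invalidateIndexes <- function(e) {
  ## indices cover rows 1..built; nt > built marks them stale. A rollback
  ## truncating nt below built forces a rebuild too:
  for (i in seq_along(e$idx)) {
    if (e$idx[[i]]$built > e$nt) e$idx[[i]]$built <- -1L
  }
  invisible(NULL)
}

.count <- function(counter, k) {
  if (!is.null(counter)) counter$n <- counter$n + k
  invisible(NULL)
}

## first position in x[lo..hi] (sorted) with x[pos] >= v, counting probes
.lowerBound <- function(x, lo, hi, v, counter) {
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    .count(counter, 1L)
    if (x[mid] < v) lo <- mid + 1L else hi <- mid - 1L
  }
  lo
}

## first position in x[lo..hi] (sorted) with x[pos] > v, counting probes
.upperBound <- function(x, lo, hi, v, counter) {
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    .count(counter, 1L)
    if (x[mid] <= v) lo <- mid + 1L else hi <- mid - 1L
  }
  lo
}

## rows: candidate triple rows; filter by remaining constrained keys,
## counting one comparison per row per key actually tested.
.residualFilter <- function(e, rows, pat, keys, counter) {
  for (k in keys) {
    if (!length(rows)) break
    .count(counter, length(rows))
    rows <- rows[.tripCol(e, k)[rows] == pat[[k]]]
  }
  rows
}

## The planner. pat: named list s/p/o/d with NA for wildcard.
## Returns list(rows = integer vector, plan = list(...)).
.findRows <- function(e, pat, counter = NULL, forceScan = FALSE) {
  n <- e$nt
  keys <- .IDX_KEYS[!vapply(.IDX_KEYS, function(k) is.na(pat[[k]]), logical(1))]
  if (!length(keys)) {
    return(list(rows = seq_len(n), plan = list(type = "all")))
  }
  best <- 0L
  bestPrefix <- 0L
  if (!forceScan) {
    for (i in seq_along(e$idx)) {
      ix <- e$idx[[i]]
      if (!(ix$bin %in% keys)) next
      pl <- 0L
      for (k in ix$sort) {
        if (k %in% keys) pl <- pl + 1L else break
      }
      if (best == 0L || pl > bestPrefix) {
        best <- i
        bestPrefix <- pl
      }
    }
  }
  if (best == 0L) {
    rows <- .residualFilter(e, seq_len(n), pat, keys, counter)
    return(list(rows = rows, plan = list(type = "scan")))
  }
  ix <- .ensureIndex(e, best)
  ord <- ix$ord
  lo <- 1L
  hi <- n
  usedKeys <- character(0)
  for (k in c(ix$bin, ix$sort[seq_len(bestPrefix)])) {
    col <- .tripCol(e, k)[ord]
    v <- pat[[k]]
    lo2 <- .lowerBound(col, lo, hi, v, counter)
    hi2 <- .upperBound(col, lo, hi, v, counter) - 1L
    lo <- lo2
    hi <- hi2
    usedKeys <- c(usedKeys, k)
    if (lo > hi) break
  }
  rows <- if (lo > hi) integer(0) else ord[lo:hi]
  rest <- setdiff(keys, usedKeys)
  rows <- .residualFilter(e, rows, pat, rest, counter)
  list(rows = rows,
       plan = list(type = "index", index = best, label = .indexLabel(e$idx[[best]]),
                   prefix = bestPrefix))
}

.asPattern <- function(subj, pred, obj, doc) {
  one <- function(x) {
    if (is.null(x) || !length(x) || is.na(x)) NA_integer_ else as.integer(x)
  }
  list(s = one(subj), p = one(pred), o = one(obj), d = one(doc))
}

#' Search triples by pattern
#'
#' Matches any combination of subject, predicate, object and source
#' document; an omitted (or `NA`) position is a wildcard, so the
#' all-wildcard pattern returns every triple. The most suitable index for
#' the pattern is selected automatically; IDs that occur in no triple
#' simply yield an empty result.
#'
#' @param store a [TripleStore].
#' @param subj,pred,obj optional integer NodeIds.
#' @param doc optional integer DocId.
#' @return a data.frame with columns `subj`, `pred`, `obj`, `doc` (one row
#'   per matching triple, in deterministic order), with the chosen query
#'   plan attached as attribute `"plan"`.
#' @examples
#' st <- TripleStore()
#' d <- registerDocument(st, "mem:example")
#' a <- internIri(st, "http://example.org/A")
#' b <- internIri(st, "http://example.org/B")
#' addTriple(st, a, vocabId("rdfs:subClassOf"), b, d)
#' findTriple(st, subj = a)
#' @export
findTriple <- function(store, subj = NULL, pred = NULL, obj = NULL, doc = NULL) {
  e <- store@ptr
  res <- .findRows(e, .asPattern(subj, pred, obj, doc))
  rows <- res$rows
  out <- data.frame(subj = e$ts[rows], pred = e$tp[rows],
                    obj = e$to[rows], doc = e$td[rows])
  attr(out, "plan") <- res$plan
  out
}

#' Does any triple match the pattern?
#' @inheritParams findTriple
#' @return `TRUE` or `FALSE`.
#' @export
anyTriple <- function(store, subj = NULL, pred = NULL, obj = NULL, doc = NULL) {
  nrow(findTriple(store, subj, pred, obj, doc)) > 0L
}

## internal: matching rows for mapper code
.matchRows <- function(e, s = NA, p = NA, o = NA, d = NA) {
  .findRows(e, .asPattern(s, p, o, d))$rows
}
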