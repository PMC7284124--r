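# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never perturbs user sessions.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive `n` independent sub-seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# All label-name bijections from the groups of `a` onto the groups of `b`
# are searched exhaustively; returns the relabelling of `b` that maximizes
# overlap with `a`. Used by aligned Hamming, dice, and consensus relabelling.
# Label sets must be small (k <= 8).
best_bijection <- function(a, b) {
  la <- sort(unique(a)); lb <- sort(unique(b))
  ka <- length(la); kb <- length(lb)
  if (kb > 8L) stop("label alignment supports at most 8 distinct labels")
  # contingency counts
  tab <- table(factor(a, levels = la), factor(b, levels = lb))
  perms <- permutations_of(seq_len(ka))
  if (kb > ka) stop("second labelling has more distinct labels than the first")
  best <- NULL; best_overlap <- -1L
  for (pr in perms) {
    # map lb[j] -> la[pr[j]] for j <= kb
    ov <- sum(tab[cbind(pr[seq_len(kb)], seq_len(kb))])
    if (ov > best_overlap) { best_overlap <- ov; best <- pr }
  }
  map <- stats::setNames(la[best[seq_len(kb)]], lb)
  list(map = map, overlap = best_overlap)
}

# All permutations of a small vector (k! rows as a list).
permutations_of <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

# Relabel `b` onto the label names of `a` by maximal-overlap bijection.
align_labels <- function(a, b) {
  bj <- best_bijection(a, b)
  unname(bj$map[as.character(b)])
}

# Canonical labels: relabel clusters 1..k in order of first appearance.
canonical_labels <- function(labels) {
  first <- unique(labels)
  match(labels, first)
}

# Next non-clobbering path: file.ext, file.1.ext, file.2.ext, ...
versioned_path <- function(path) {
  if (!file.exists(path)) return(path)
  base <- tools::file_path_sans_ext(path)
  ext <- tools::file_ext(path)
  i <- 1L
  repeat {
    cand <- if (nzchar(ext)) sprintf("%s.%d.%s", base, i, ext) else sprintf("%s.%d", base, i)
    if (!file.exists(cand)) return(cand)
    i <- i + 1L
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
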