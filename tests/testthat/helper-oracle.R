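# Independent reference implementation of the cluster test, used as the
# enumeration oracle: per-timepoint t via apply, rle-based cluster
# extraction, exhaustive sign-flip null. Deliberately shares no code with
# cluster_permutation().
oracle_cluster_p <- function(x, alpha_point = 0.05) {
  n <- nrow(x)
  tstat <- function(m) apply(m, 2, function(v) mean(v) / (sd(v) / sqrt(length(v))))
  crit <- qt(1 - alpha_point / 2, n - 1)
  find_clusters <- function(tv) {
    code <- ifelse(abs(tv) > crit, sign(tv), 0)
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != 0
    data.frame(start = starts[keep], end = ends[keep],
               mass = mapply(function(s, e) sum(tv[s:e]), starts[keep], ends[keep]))
  }
  obs <- find_clusters(tstat(x))
  all_signs <- expand.grid(rep(list(c(-1, 1)), n))
  null_max <- apply(all_signs, 1, function(s) {
    cl <- find_clusters(tstat(x * s))
    if (nrow(cl) == 0) 0 else max(abs(cl$mass))
  })
  obs$p <- vapply(
    obs$mass, function(m) mean(null_max >= abs(m) - 1e-12), numeric(1)
  )
  obs
}
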