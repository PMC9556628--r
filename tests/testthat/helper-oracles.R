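# Independent oracles and small state builders shared across test files.

# breadth-first connected-component census, independent of the union-find
# implementation under test
bfs_census <- function(n_nodes, edges = NULL) {
  adj <- vector("list", n_nodes)
  if (!is.null(edges) && NROW(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- logical(n_nodes)
  sizes <- integer(0)
  for (v in seq_len(n_nodes)) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    count <- 0L
    while (length(queue) > 0L) {
      x <- queue[[1L]]
      queue <- queue[-1L]
      count <- count + 1L
      for (w in adj[[x]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    sizes <- c(sizes, count)
  }
  sort(sizes, decreasing = TRUE)
}

# AB state that is a single open chain of k units (k+1 nodes, 2 tips)
chain_state <- function(k) {
  structure(list(Ne = as.integer(k), units = cbind(1:k, 2:(k + 1L))),
            class = "ab_state")
}

# degree table of an AB state's unit graph
state_degrees <- function(state) {
  deg <- tabulate(state$units, nbins = max(state$units))
  deg[deg > 0L]
}
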