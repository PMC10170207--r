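#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

#' Topological order of a pedigree (parents before offspring)
#'
#' Kahn's algorithm over parent-to-child edges. Errors if the parent links
#' contain a cycle, reporting the individuals involved.
#'
#' @param id,sire,dam character vectors of equal length; `NA` for unknown.
#' @return integer permutation of `seq_along(id)`.
#' @keywords internal
topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- unname(idx[sire])
  di <- unname(idx[dam])
  indeg <- integer(n)
  indeg[!is.na(si)] <- indeg[!is.na(si)] + 1L
  indeg[!is.na(di)] <- indeg[!is.na(di)] + 1L
  # children adjacency: parent index -> child indices
  par <- c(si, di)
  chl <- c(seq_len(n), seq_len(n))
  keep <- !is.na(par)
  adj <- split(chl[keep], par[keep])
  out <- integer(n)
  queue <- which(indeg == 0L)
  k <- 0L
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    k <- k + 1L
    out[k] <- v
    kids <- adj[[as.character(v)]]
    for (w in kids) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (k < n) {
    stuck <- id[indeg > 0L]
    stop("cycle in parent links involving: ", paste(utils::head(stuck, 10), collapse = ", "))
  }
  out
}

# mode of a posterior sample via kernel density argmax (Silverman bandwidth)
density_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) return(x[1L])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

# deterministic per-purpose seed fan-out from one master seed (keeps values
# within the 32-bit integer range R requires)
split_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}
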