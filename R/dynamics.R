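#' Advance a Boolean network one synchronous step
#'
#' All genes evaluate their transition functions simultaneously on the current
#' state.
#'
#' @param net A [boolean_network()].
#' @param state Binary vector of length `n` in gene order (names optional).
#' @return Named integer 0/1 vector: the successor state.
#' @examples
#' net <- parse_boolnet("targets, factors\nA, C\nB, A & C\nC, !B")
#' synchronous_step(net, c(0, 0, 0))
#' @export
synchronous_step <- function(net, state) {
  n <- length(net$genes)
  if (length(state) != n) stop("state length ", length(state), " != ", n, " genes")
  state <- as.integer(state)
  if (!all(state %in% c(0L, 1L))) stop("state entries must be 0 or 1")
  names(state) <- net$genes
  out <- vapply(net$genes, function(g) eval_bn_function(net$functions[[g]], state),
                integer(1))
  stats::setNames(out, net$genes)
}

# Decode integers 0..2^n-1 into a (length(x) x n) 0/1 matrix, gene 1 = MSB.
int_to_states <- function(x, n) {
  m <- vapply((n - 1L):0L, function(pos) bit_at(x, pos), integer(length(x)))
  matrix(m, nrow = length(x), ncol = n)
}

states_to_int <- function(m) as.integer(m %*% 2L^((ncol(m) - 1L):0L))

# Full synchronous transition map over all 2^n states (1-indexed successor of
# state i-1 is map[i]). Vectorized over states; used by the exhaustive search.
transition_map <- function(net) {
  n <- length(net$genes)
  states <- 0:(2^n - 1L)
  nxt <- numeric(length(states))
  for (j in seq_len(n)) {
    f <- net$functions[[j]]
    k <- length(f$inputs)
    if (k == 0) {
      out <- rep(f$table[1L], length(states))
    } else {
      idx <- integer(length(states))
      for (m in seq_len(k)) {
        jj <- match(f$inputs[m], net$genes)
        idx <- idx * 2L + bit_at(states, n - jj)
      }
      out <- f$table[idx + 1L]
    }
    nxt <- nxt + out * 2^(n - j)
  }
  as.integer(nxt) + 1L
}

#' Summarize an attractor cycle as a trinary vector
#'
#' Each gene is summarized as its constant value over the cycle (0 or 1), or
#' 0.5 if it oscillates.
#'
#' @param cycle Matrix of cycle states (rows = consecutive states, columns =
#'   genes) or a list of state vectors.
#' @param net Optional [boolean_network()]; when given, the cycle is verified
#'   to be a genuine synchronous cycle (each state maps to the next, the last
#'   back to the first).
#' @return Numeric vector in \{0, 0.5, 1\} per gene.
#' @export
summarize_attractor <- function(cycle, net = NULL) {
  if (is.list(cycle)) cycle <- do.call(rbind, cycle)
  if (!is.matrix(cycle)) cycle <- matrix(cycle, nrow = 1)
  if (!is.null(net)) {
    for (i in seq_len(nrow(cycle))) {
      succ <- synchronous_step(net, cycle[i, ])
      nxt <- cycle[if (i == nrow(cycle)) 1L else i + 1L, ]
      if (!all(succ == nxt)) {
        stop("not a synchronous cycle: state ", i, " does not map to its successor")
      }
    }
  }
  apply(cycle, 2, function(col) if (all(col == col[1])) col[1] else 0.5)
}

#' Find the attractors of a Boolean network
#'
#' Under synchronous updating every trajectory ends in a recurring state or
#' cycle of states (an attractor). `mode = "exhaustive"` follows every one of
#' the `2^n` states (via a vectorized transition map and pointer doubling) and
#' returns all attractors together with basin sizes; it is limited to
#' `n <= exhaustive_limit` genes. `mode = "sampled"` follows trajectories from
#' `n_starts` random initial states and returns the attractors reached — a
#' subset of the true attractor set, reproducible through `seed`.
#'
#' @param net A [boolean_network()].
#' @param mode `"exhaustive"` (default) or `"sampled"`.
#' @param n_starts Number of random starts in sampled mode; default
#'   `min(2^n, 100000)`.
#' @param seed Integer seed, required in sampled mode (unless `starts` is
#'   given).
#' @param starts Optional 0/1 matrix of initial states (rows = states,
#'   columns = genes) for sampled mode, overriding `n_starts`/`seed`.
#' @param exhaustive_limit Largest `n` allowed in exhaustive mode (default 25).
#' @return A tibble of class `bn_attractors`: one row per attractor with
#'   columns `attractor` (id), `length` (cycle length), `basin` (basin size;
#'   `NA` in sampled mode) and one trinary summary column per gene. The raw
#'   cycles (matrices of states) are kept in attribute `"cycles"`.
#' @examples
#' net <- parse_boolnet("targets, factors\nA, C\nB, A & C\nC, !B")
#' find_attractors(net)
#' @export
find_attractors <- function(net, mode = c("exhaustive", "sampled"),
                            n_starts = NULL, seed = NULL,
                            exhaustive_limit = 25, starts = NULL) {
  mode <- match.arg(mode)
  n <- length(net$genes)
  if (mode == "exhaustive") {
    if (n > exhaustive_limit) {
      stop("exhaustive attractor search requires n <= ", exhaustive_limit,
           " genes (got ", n, "); use mode = \"sampled\" with a seed")
    }
    find_attractors_exhaustive(net)
  } else {
    if (is.null(starts)) {
      if (is.null(seed)) stop("sampled mode requires a `seed`")
      if (is.null(n_starts)) n_starts <- min(2^n, 100000)
      starts <- with_local_seed(seed, {
        matrix(as.integer(stats::runif(n_starts * n) < 0.5),
               nrow = n_starts, ncol = n)
      })
    }
    find_attractors_sampled(net, starts)
  }
}

find_attractors_exhaustive <- function(net) {
  n <- length(net$genes)
  map <- transition_map(net)
  # pointer doubling: after n squarings every state has been advanced >= 2^n
  # steps, hence lies on its attractor cycle
  f <- map
  for (i in seq_len(max(1L, n))) f <- f[f]
  cyc_state <- f  # one on-cycle state per starting state

  reps <- unique(cyc_state)
  cycles <- list()
  canon_of <- integer(0)  # canonical (minimum) cycle state per representative
  for (r in reps) {
    cyc <- r
    s <- map[r]
    while (s != r) {
      cyc <- c(cyc, s)
      s <- map[s]
    }
    canon <- min(cyc)
    if (!as.character(canon) %in% names(cycles)) {
      # rotate so the cycle starts at its canonical state
      shift <- which(cyc == canon)
      cycles[[as.character(canon)]] <- c(cyc[shift:length(cyc)],
                                         cyc[seq_len(shift - 1L)])
    }
    canon_of[as.character(r)] <- canon
  }
  basin <- table(canon_of[as.character(cyc_state)])
  canon_sorted <- sort(as.integer(names(cycles)))
  cycle_mats <- lapply(as.character(canon_sorted), function(key) {
    m <- int_to_states(cycles[[key]] - 1L, n)
    colnames(m) <- net$genes
    m
  })
  build_attractor_tibble(net, cycle_mats,
                         basin = as.integer(basin[as.character(canon_sorted)]),
                         mode = "exhaustive")
}

find_attractors_sampled <- function(net, starts) {
  n <- length(net$genes)
  if (ncol(starts) != n) stop("`starts` must have one column per gene")
  seen <- new.env(parent = emptyenv(), hash = TRUE)  # state key -> attractor id
  cycle_mats <- list()
  hits <- integer(0)
  key_of <- function(s) paste(s, collapse = "")

  for (i in seq_len(nrow(starts))) {
    s <- starts[i, ]
    path_keys <- character(0)
    path_states <- list()
    repeat {
      key <- key_of(s)
      known <- seen[[key]]
      if (!is.null(known)) {
        id <- known
        break
      }
      pos <- match(key, path_keys)
      if (!is.na(pos)) {
        # new cycle discovered: states pos..end of the path
        cyc <- do.call(rbind, path_states[pos:length(path_states)])
        colnames(cyc) <- net$genes
        canon <- which.min(states_to_int(cyc))
        cyc <- cyc[c(canon:nrow(cyc), seq_len(canon - 1L)), , drop = FALSE]
        id <- length(cycle_mats) + 1L
        cycle_mats[[id]] <- cyc
        hits[id] <- 0L
        break
      }
      path_keys <- c(path_keys, key)
      path_states[[length(path_states) + 1L]] <- s
      s <- unname(synchronous_step(net, s))
    }
    for (k in path_keys) seen[[k]] <- id
    hits[id] <- hits[id] + 1L
  }
  ord <- order(vapply(cycle_mats, function(m) states_to_int(m)[1], integer(1)))
  build_attractor_tibble(net, cycle_mats[ord], basin = NA_integer_,
                         mode = "sampled", starts_reaching = hits[ord])
}

build_attractor_tibble <- function(net, cycle_mats, basin, mode,
                                   starts_reaching = NULL) {
  summaries <- lapply(cycle_mats, summarize_attractor)
  summ_mat <- do.call(rbind, summaries)
  colnames(summ_mat) <- net$genes
  out <- tibble::tibble(
    attractor = seq_along(cycle_mats),
    length = vapply(cycle_mats, nrow, integer(1)),
    basin = basin
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(summ_mat))
  attr(out, "cycles") <- cycle_mats
  attr(out, "mode") <- mode
  attr(out, "genes") <- net$genes
  if (!is.null(starts_reaching)) attr(out, "starts_reaching") <- starts_reaching
  class(out) <- c("bn_attractors", class(out))
  out
}

#' Extract the trinary summary matrix from an attractor table
#'
#' @param attractors A `bn_attractors` tibble from [find_attractors()].
#' @return Numeric matrix, one row per attractor, one column per gene.
#' @export
attractor_summaries <- function(attractors) {
  genes <- attr(attractors, "genes")
  as.matrix(attractors[, genes, drop = FALSE])
}

#' Fix a gene by knock-out or over-expression
#'
#' Replaces the gene's transition function with the constant 0 (knock-out) or
#' 1 (over-expression); all other functions are untouched. The perturbed gene
#' thus holds its forced value from the first update onward.
#'
#' @param net A [boolean_network()].
#' @param gene Gene to perturb.
#' @param type `"KO"` or `"OE"`.
#' @return The perturbed [boolean_network()].
#' @export
apply_perturbation <- function(net, gene, type = c("KO", "OE")) {
  type <- match.arg(type)
  if (!gene %in% net$genes) stop("unknown gene: ", gene)
  net$functions[[gene]] <- bn_function(character(0),
                                       if (type == "KO") 0L else 1L)
  net$name <- paste0(net$name, "_", type, "_", gene)
  net
}
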