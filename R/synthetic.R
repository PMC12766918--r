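#' Scale-free benchmark network
#'
#' Preferential attachment (Barabasi-Albert) generator: node i joins with
#' `min(m, i - 1)` edges to existing nodes chosen proportionally to degree,
#' so with `m = 2` the edge count is the closed form
#' \eqn{\sum_i \min(2, i-1) = 2n - 3} — twice as many edges as nodes, up to
#' the constant seed deficit. The graph is connected and simple; node ids
#' are zero-padded (`n000001`, ...) so canonical lexicographic order equals
#' construction order.
#'
#' @param n number of nodes (> m)
#' @param m edges attached per arriving node (default 2)
#' @param seed RNG seed
#' @return a `netkin_network`
#' @export
gen_scale_free <- function(n, m = 2L, seed = 42L) {
  if (n <= m) stop("n must exceed m")
  g <- with_seed(seed, igraph::sample_pa(n, m = m, directed = FALSE,
                                         algorithm = "psumtree"))
  width <- nchar(as.character(n))
  g <- igraph::set_vertex_attr(g, "name",
                               value = sprintf("n%0*d", width, seq_len(n)))
  from_igraph(g)
}

#' Simulated annotation table
#'
#' Draws term sizes i.i.d. from a heavy-tailed distribution emulating GO
#' Biological Process membership counts — default a discrete power law with
#' exponent 1.5 truncated to `[5, n/10]` — and fills each term with members
#' sampled uniformly without replacement, independent of topology (a null
#' annotation model).
#'
#' @param net a `netkin_network`
#' @param n_terms number of terms (default 1000)
#' @param dist list describing the size law: `law` (`"powerlaw"` or
#'   `"lognormal"`), `min`, `max`, and `exponent` (powerlaw) or
#'   `meanlog`/`sdlog` (lognormal). `min`/`max` default to 5 and
#'   `floor(n/10)`.
#' @param seed RNG seed
#' @param min_size size filter forwarded to the matrix builder (default 1:
#'   generated terms are kept as drawn)
#' @return a `netkin_annotation`
#' @export
gen_annotations <- function(net, n_terms = 1000L, dist = list(), seed = 42L,
                            min_size = 1L) {
  stopifnot(inherits(net, "netkin_network"))
  if (n_terms < 1) stop("n_terms must be >= 1")
  n <- length(net$nodes)
  law <- dist$law %||% "powerlaw"
  lo <- dist$min %||% 5L
  hi <- dist$max %||% max(lo, floor(n / 10))
  if (lo < 1 || hi < lo || hi > n)
    stop("infeasible term-size bounds [", lo, ", ", hi, "] for ", n, " nodes")
  sizes_support <- lo:hi
  prob <- switch(law,
    powerlaw = sizes_support^-(dist$exponent %||% 1.5),
    lognormal = stats::dlnorm(sizes_support, dist$meanlog %||% log(30),
                              dist$sdlog %||% 1),
    stop("unknown size law '", law, "'"))
  width <- nchar(as.character(n_terms))
  mapping <- with_seed(seed, {
    sizes <- if (length(sizes_support) == 1) rep(lo, n_terms)
             else sample(sizes_support, n_terms, replace = TRUE, prob = prob)
    lapply(sizes, function(k) sample(net$nodes, k))
  })
  names(mapping) <- sprintf("T%0*d", width, seq_len(n_terms))
  build_matrix(mapping, net, min_size = min_size, max_size = n)
}

#' Planted-partition fixture
#'
#' Stochastic block model with `blocks` equal blocks of `size` nodes,
#' within-block edge probability `p_in` and between-block probability
#' `p_out`, plus the ground-truth partition. With `coherent_terms`, one
#' signal term per block covers a seeded 80% subset of that block, and
#' `n_decoys` decoy terms are drawn uniformly at random (sizes from the
#' default annotation size law), giving a fixture where exactly the
#' (block, signal term) pairs carry real overrepresentation signal.
#'
#' @param blocks number of blocks (default 4)
#' @param size nodes per block (default 25)
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`
#' @param seed RNG seed
#' @param coherent_terms generate the signal + decoy annotation matrix
#' @param n_decoys number of decoy terms (default 16)
#' @return list with `network`, `truth` (a `netkin_partition`),
#'   `annotations` (`netkin_annotation` or NULL), `signal_terms` (named by
#'   block cluster id)
#' @export
gen_planted <- function(blocks = 4L, size = 25L, p_in = 0.5, p_out = 0.02,
                        seed = 42L, coherent_terms = TRUE, n_decoys = 16L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1")
  if (p_out == 0)
    warning("p_out = 0: the expected graph is disconnected (components = blocks)")
  n <- blocks * size
  pref <- matrix(p_out, blocks, blocks)
  diag(pref) <- p_in
  g <- with_seed(seed, igraph::sample_sbm(n, pref.matrix = pref,
                                          block.sizes = rep(size, blocks)))
  width <- nchar(as.character(n))
  ids <- sprintf("n%0*d", width, seq_len(n))
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  net <- from_igraph(g)
  block_of <- rep(seq_len(blocks) - 1L, each = size)
  truth <- as_partition(stats::setNames(block_of, ids),
                        params = list(algorithm = "planted", seed = seed))

  ann <- NULL
  signal_terms <- NULL
  if (coherent_terms) {
    mapping <- with_seed(seed + 1L, {
      sig <- lapply(seq_len(blocks), function(b) {
        members <- ids[block_of == (b - 1L)]
        sample(members, max(2L, round(0.8 * size)))
      })
      names(sig) <- sprintf("signal_block%d", seq_len(blocks) - 1L)
      dec <- list()
      if (n_decoys > 0) {
        lo <- 5L; hi <- max(6L, floor(n / 10))
        szs <- sample(lo:hi, n_decoys, replace = TRUE, prob = (lo:hi)^-1.5)
        dec <- lapply(szs, function(k) sample(ids, k))
        names(dec) <- sprintf("decoy%02d", seq_len(n_decoys))
      }
      c(sig, dec)
    })
    ann <- build_matrix(mapping, net, min_size = 1L, max_size = n)
    signal_terms <- stats::setNames(sprintf("signal_block%d", seq_len(blocks) - 1L),
                                    as.character(seq_len(blocks) - 1L))
  }
  list(network = net, truth = truth, annotations = ann,
       signal_terms = signal_terms)
}
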