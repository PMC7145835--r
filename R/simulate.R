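#' Configuration for the planted-partition PPI benchmark
#'
#' Defines the synthetic study conditions: `n_blocks` dense communities of
#' `block_size` nodes each (within-block edge probability `p_in`,
#' between-block probability `p_out`), plus `n_bridges` designated bridge
#' nodes that belong to no block and send `bridge_degree` edges into every
#' block — the sparse gateways the betweenness ranking is meant to
#' recover. Disease sets A and B each receive all bridges plus disjoint
#' fractions (`set_a_frac`, `set_b_frac`) of the block nodes; the
#' drug-perturbation set receives `drug_bridge_count` bridges plus random
#' block-node fillers up to `drug_set_size`.
#'
#' @param n_blocks,block_size Number and size of planted blocks.
#' @param p_in,p_out Within- and between-block edge probabilities;
#'   0 <= p_out < p_in <= 1.
#' @param n_bridges Number of bridge nodes; must not exceed
#'   `drug_set_size`.
#' @param bridge_degree Edges each bridge sends into each block.
#' @param set_a_frac,set_b_frac Fractions of block nodes sampled
#'   (disjointly) into disease sets A and B; must sum to at most 1.
#' @param drug_set_size Total size of the drug-perturbation set.
#' @param drug_bridge_count Bridges forced into the drug set (<= n_bridges).
#' @param seed Integer seed; one seed drives the whole generator, with
#'   per-stage sub-streams so adding a stage never perturbs earlier draws.
#' @return A `planted_config` list.
#' @export
planted_config <- function(n_blocks = 4, block_size = 25,
                           p_in = 0.3, p_out = 0.01,
                           n_bridges = 4, bridge_degree = 3,
                           set_a_frac = 0.6, set_b_frac = 0.3,
                           drug_set_size = 12, drug_bridge_count = 4,
                           seed = 1) {
  cfg <- list(n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
              p_in = p_in, p_out = p_out,
              n_bridges = as.integer(n_bridges), bridge_degree = as.integer(bridge_degree),
              set_a_frac = set_a_frac, set_b_frac = set_b_frac,
              drug_set_size = as.integer(drug_set_size),
              drug_bridge_count = as.integer(drug_bridge_count),
              seed = as.integer(seed))
  validate_planted_config(cfg)
  structure(cfg, class = "planted_config")
}

validate_planted_config <- function(cfg) {
  bad <- function(msg) abort(paste0("Invalid planted config: ", msg),
                             class = "triplefocus_invalid_config")
  with(cfg, {
    if (n_blocks < 1 || block_size < 1 || n_bridges < 0 || bridge_degree < 1 ||
        drug_set_size < 1 || drug_bridge_count < 0) {
      bad("counts must be positive.")
    }
    if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) bad("need 0 <= p_out < p_in <= 1.")
    if (n_bridges > drug_set_size) bad("n_bridges must not exceed drug_set_size.")
    if (drug_bridge_count > n_bridges) bad("drug_bridge_count must not exceed n_bridges.")
    if (bridge_degree > block_size) bad("bridge_degree must not exceed block_size.")
    if (p_in * (block_size - 1) < 1 && block_size > 1) {
      bad("expected within-block degree p_in*(block_size-1) < 1; blocks would fall apart.")
    }
    if (block_size == 1 && p_in < 1) bad("block_size 1 requires p_in = 1.")
    if (set_a_frac < 0 || set_b_frac < 0 || set_a_frac + set_b_frac > 1) {
      bad("set fractions must be non-negative and sum to at most 1.")
    }
    invisible(NULL)
  })
  invisible(cfg)
}

# per-stage sub-seed derived from the single user seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + stage * 104729) %% 2147483629)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a planted-partition PPI benchmark graph
#'
#' Samples the synthetic network described by [planted_config()]: dense
#' blocks, sparse between-block edges, and bridge nodes wired with
#' `bridge_degree` edges into every block. Edge confidence scores are
#' drawn uniformly from 401--1000 so the default medium-confidence filter
#' (score > 400) keeps every generated edge. Deterministic given the
#' config seed.
#'
#' @param config A [planted_config()].
#' @return List with `edges` (interaction tibble: node_a, node_b, score)
#'   and `truth` (a `planted_truth`: `block_of` named integer vector over
#'   block nodes, `bridges`, `pathway_of_block`, and the generating
#'   config).
#' @export
generate_planted_network <- function(config) {
  stopifnot(inherits(config, "planted_config"))
  cfg <- config
  n_block_nodes <- cfg$n_blocks * cfg$block_size
  total <- n_block_nodes + cfg$n_bridges
  width <- max(4, nchar(total))
  sym <- sprintf(paste0("G%0", width, "d"), seq_len(total))
  block_of <- stats::setNames(rep(seq_len(cfg$n_blocks), each = cfg$block_size),
                              sym[seq_len(n_block_nodes)])
  bridges <- if (cfg$n_bridges > 0) sym[n_block_nodes + seq_len(cfg$n_bridges)] else character(0)

  from <- character(0); to <- character(0)
  with_local_seed(stage_seed(cfg$seed, 1L), {
    # within-block edges
    for (b in seq_len(cfg$n_blocks)) {
      mem <- names(block_of)[block_of == b]
      if (length(mem) >= 2) {
        pr <- utils::combn(mem, 2)
        keep <- runif(ncol(pr)) < cfg$p_in
        from <- c(from, pr[1, keep]); to <- c(to, pr[2, keep])
      }
    }
    # between-block (non-bridge) edges
    if (cfg$p_out > 0 && cfg$n_blocks >= 2) {
      for (b1 in seq_len(cfg$n_blocks - 1)) {
        for (b2 in seq(b1 + 1, cfg$n_blocks)) {
          m1 <- names(block_of)[block_of == b1]
          m2 <- names(block_of)[block_of == b2]
          pr <- expand.grid(a = m1, b = m2, stringsAsFactors = FALSE)
          keep <- runif(nrow(pr)) < cfg$p_out
          from <- c(from, pr$a[keep]); to <- c(to, pr$b[keep])
        }
      }
    }
    # bridges: bridge_degree edges into every block
    for (br in bridges) {
      for (b in seq_len(cfg$n_blocks)) {
        mem <- names(block_of)[block_of == b]
        tgt <- sample(mem, cfg$bridge_degree)
        from <- c(from, rep(br, length(tgt))); to <- c(to, tgt)
      }
    }
    score <- sample(401:1000, length(from), replace = TRUE)
    edges <- tibble::tibble(node_a = pmin(from, to), node_b = pmax(from, to),
                             score = as.integer(score))
  })
  edges <- collapse_duplicate_pairs(edges)
  truth <- structure(
    list(
      block_of = block_of,
      bridges = bridges,
      pathway_of_block = stats::setNames(
        sprintf("BLOCK%d_PATHWAY", seq_len(cfg$n_blocks)), seq_len(cfg$n_blocks)),
      config = cfg
    ),
    class = "planted_truth"
  )
  list(edges = edges, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d blocks x %d nodes, %d bridges\n",
              x$config$n_blocks, x$config$block_size, length(x$bridges)))
  invisible(x)
}

#' Sample disease and drug-perturbation gene sets from a planted network
#'
#' Disease sets A and B each contain every planted bridge plus disjointly
#' sampled block nodes, so A intersect B is exactly the bridge set. The
#' drug set contains the first `drug_bridge_count` bridges (by symbol)
#' plus random block-node fillers, so the triple overlap A, B, drug
#' contains exactly those planted bridges. Deterministic given the config
#' seed.
#'
#' @param truth `planted_truth` from [generate_planted_network()].
#' @param config The same [planted_config()] (defaults to the one stored
#'   in `truth`).
#' @return Named list of three [gene_set]s: `set_a`, `set_b`, `drug_set`.
#' @export
generate_gene_sets <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "planted_config"))
  cfg <- config
  non_bridge <- sort(names(truth$block_of))
  n_a <- floor(cfg$set_a_frac * length(non_bridge))
  n_b <- floor(cfg$set_b_frac * length(non_bridge))
  if (n_a + n_b > length(non_bridge)) {
    abort("Invalid planted config: requested set fractions exceed available nodes.",
          class = "triplefocus_invalid_config")
  }
  n_fill <- cfg$drug_set_size - cfg$drug_bridge_count
  if (n_fill > length(non_bridge)) {
    abort("Invalid planted config: drug set larger than available nodes.",
          class = "triplefocus_invalid_config")
  }
  with_local_seed(stage_seed(cfg$seed, 2L), {
    a_nodes <- sort(sample(non_bridge, n_a))
    b_nodes <- sort(sample(setdiff(non_bridge, a_nodes), n_b))
    fillers <- sort(sample(non_bridge, n_fill))
    drug_bridges <- head(sort(truth$bridges), cfg$drug_bridge_count)
    sets <- list(
      set_a = gene_set("disease_a", c(truth$bridges, a_nodes)),
      set_b = gene_set("disease_b", c(truth$bridges, b_nodes)),
      drug_set = gene_set("drug_perturbed", c(drug_bridges, fillers))
    )
  })
  sets
}

#' Generate block-aligned pathway gene sets
#'
#' One pathway per planted block: the block's member set with a fraction
#' `noise_frac` of members swapped for random nodes outside the block
#' (bridges or other blocks' members). With `noise_frac = 0` each pathway
#' equals its block exactly. Deterministic given the config seed.
#'
#' @param truth `planted_truth` from [generate_planted_network()].
#' @param noise_frac Fraction of each block's members to swap out;
#'   0 <= noise_frac < 0.5.
#' @return A `pathway_collection` tibble (GMT-writable via [write_gmt()]).
#' @export
generate_pathways <- function(truth, noise_frac = 0.1) {
  stopifnot(inherits(truth, "planted_truth"))
  if (!(noise_frac >= 0 && noise_frac < 0.5)) {
    abort("Invalid planted config: need 0 <= noise_frac < 0.5.",
          class = "triplefocus_invalid_config")
  }
  cfg <- truth$config
  all_nodes <- c(names(truth$block_of), truth$bridges)
  with_local_seed(stage_seed(cfg$seed, 3L), {
    genes <- lapply(seq_len(cfg$n_blocks), function(b) {
      mem <- sort(names(truth$block_of)[truth$block_of == b])
      n_swap <- floor(noise_frac * length(mem))
      if (n_swap > 0) {
        out <- sample(mem, n_swap)
        pool <- setdiff(all_nodes, mem)
        repl <- sample(pool, n_swap)
        mem <- c(setdiff(mem, out), repl)
      }
      sort(mem)
    })
    pwys <- new_pathway_collection(
      pathway = unname(truth$pathway_of_block),
      source_id = sprintf("SYN%04d", seq_len(cfg$n_blocks)),
      genes = genes
    )
  })
  pwys
}

#' Write the planted ground truth as TSV
#'
#' @param truth A `planted_truth`.
#' @param path Output path; columns `node`, `block` (0 for bridges),
#'   `is_bridge`.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  tbl <- tibble::tibble(
    node = c(names(truth$block_of), truth$bridges),
    block = c(unname(truth$block_of), rep(0L, length(truth$bridges))),
    is_bridge = c(rep(FALSE, length(truth$block_of)), rep(TRUE, length(truth$bridges)))
  ) |> dplyr::arrange(.data$node)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
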