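# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Crosslink simulation parameters
#'
#' Defaults reproduce the CASP15-style study conditions: 10% sequence
#' coverage on the longer sequence and a 20% expected false-discovery rate.
#'
#' @param coverage Fraction of the longer sequence covered by true links,
#'   in (0, 1].
#' @param fdr Expected fraction of incorrect (decoy) links, in [0, 1).
#' @param seed Integer seed; all randomness of a simulation flows from it.
#' @param scope Which chain relations to simulate: `"both"` runs the
#'   inter-chain scope plus one intra-chain scope per chain, independently.
#' @return An `xl_sim_params` list.
#' @export
simulation_params <- function(coverage = 0.1, fdr = 0.2, seed = 1L,
                              scope = c("both", "inter", "intra")) {
  scope <- match.arg(scope)
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  if (fdr < 0 || fdr >= 1) stop("fdr must be in [0, 1)")
  structure(list(coverage = coverage, fdr = fdr, seed = as.integer(seed),
                 scope = scope), class = "xl_sim_params")
}

#' Construct a crosslink set
#'
#' A crosslink set is a table of unordered residue-pair links with decoy
#' flags and link-level FDRs, plus the simulation parameters that produced
#' it (when simulated). Links must reference distinct residues and contain
#' no duplicate unordered pairs.
#'
#' @param links data.frame with columns `chain1`, `res1`, `chain2`, `res2`
#'   and optionally `is_decoy` (logical, `NA` when unknown) and `link_fdr`.
#' @param params An [simulation_params()] or `NULL`.
#' @param source Free-text identifier of the source structure.
#' @return An `xl_crosslink_set`.
#' @export
crosslink_set <- function(links, params = NULL, source = "") {
  links <- as.data.frame(links)
  need <- c("chain1", "res1", "chain2", "res2")
  if (!all(need %in% names(links)))
    stop("links need columns ", paste(need, collapse = ", "))
  if (!"is_decoy" %in% names(links)) links$is_decoy <- rep(NA, nrow(links))
  if (!"link_fdr" %in% names(links))
    links$link_fdr <- rep(NA_real_, nrow(links))
  links <- links[c(need, "is_decoy", "link_fdr")]
  if (any(links$chain1 == links$chain2 & links$res1 == links$res2))
    stop("a crosslink cannot join a residue to itself")
  key <- ifelse(
    links$chain1 < links$chain2 |
      (links$chain1 == links$chain2 & links$res1 <= links$res2),
    paste(links$chain1, links$res1, links$chain2, links$res2),
    paste(links$chain2, links$res2, links$chain1, links$res1))
  if (anyDuplicated(key))
    stop("duplicate unordered residue pair in crosslink set")
  new_crosslink_set(links, params, source)
}

new_crosslink_set <- function(links, params, source = "") {
  rownames(links) <- NULL
  structure(list(links = links, params = params, source = source),
            class = "xl_crosslink_set")
}

#' @export
print.xl_crosslink_set <- function(x, ...) {
  nd <- sum(x$links$is_decoy)
  cat("xl_crosslink_set: ", nrow(x$links), " links (", nd, " decoys",
      if (nrow(x$links)) sprintf(", realised FDR %.3f", nd / nrow(x$links)),
      ") from ", x$source, "\n", sep = "")
  invisible(x)
}

empty_links <- function() {
  data.frame(chain1 = character(), res1 = integer(),
             chain2 = character(), res2 = integer(),
             is_decoy = logical(), link_fdr = numeric(),
             stringsAsFactors = FALSE)
}

# CA-bearing residue table with one-letter codes and coordinates.
ca_table <- function(s) {
  do.call(rbind, lapply(chain_ids(s), function(ch) {
    res <- chain_residues(s, ch)
    seq1 <- strsplit(chain_sequence(s, ch), "")[[1]]
    keep <- res$has_ca
    m <- ca_matrix(s, ch)
    data.frame(chain = ch, resno = res$resno[keep], aa = seq1[keep],
               x = m[, 1], y = m[, 2], z = m[, 3],
               stringsAsFactors = FALSE)
  }))
}

#' Precompute chemistry and candidate pools for a structure
#'
#' Runs tryptic digestion and Shrake-Rupley SASA once and derives, per
#' scope, the crosslink candidate pool (both residues crosslinkable,
#' CA-CA distance within the crosslinker bound) and the decoy pool
#' (CA-CA distance above the bound, at least one Lys/Ser/Thr/Tyr).
#' Passing the result to the simulation functions avoids recomputing
#' SASA across seeds; it does not change any result.
#'
#' @param s An `xl_structure`.
#' @param profile An [crosslinker_profile()].
#' @param ... Passed to [digest_trypsin()] and [shrake_rupley()]
#'   (`max_missed`, `min_len`, `max_len`, `probe_radius`, `n_points`,
#'   `rel_cutoff`).
#' @return An `xl_prep` object.
#' @export
xl_prep <- function(s, profile, ...) {
  dots <- list(...)
  darg <- dots[intersect(names(dots), c("max_missed", "min_len", "max_len"))]
  sarg <- dots[intersect(names(dots), c("probe_radius", "n_points",
                                        "rel_cutoff"))]
  digest <- lapply(chain_ids(s), function(ch)
    do.call(digest_trypsin, c(list(chain_sequence(s, ch)), darg)))
  names(digest) <- chain_ids(s)
  sasa <- do.call(shrake_rupley, c(list(s), sarg))
  tab  <- ca_table(s)
  key  <- paste(tab$chain, tab$resno)
  xl1  <- crosslinkable_residues(s, profile$side1, digest, sasa)
  xl2  <- crosslinkable_residues(s, profile$side2, digest, sasa)
  in1  <- key %in% paste(xl1$chain, xl1$resno)
  in2  <- key %in% paste(xl2$chain, xl2$resno)
  D    <- as.matrix(stats::dist(tab[, c("x", "y", "z")]))
  ktsy <- tab$aa %in% c("K", "S", "T", "Y")

  ut <- which(upper.tri(D), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  eligible <- (in1[i] & in2[j]) | (in2[i] & in1[j])
  pools <- function(mask) {
    p <- data.frame(chain1 = tab$chain[i], res1 = tab$resno[i],
                    chain2 = tab$chain[j], res2 = tab$resno[j],
                    dist = D[cbind(i, j)],
                    stringsAsFactors = FALSE)[mask, , drop = FALSE]
    # canonical unordered-pair order: (chain id, residue number)
    swap <- p$chain1 > p$chain2 | (p$chain1 == p$chain2 & p$res1 > p$res2)
    p[swap, c("chain1", "res1", "chain2", "res2")] <-
      p[swap, c("chain2", "res2", "chain1", "res1")]
    p <- p[order(p$chain1, p$res1, p$chain2, p$res2), , drop = FALSE]
    rownames(p) <- NULL
    p
  }
  scopes <- list()
  inter_mask <- tab$chain[i] != tab$chain[j]
  scopes[["inter"]] <- list(
    candidates = pools(eligible & inter_mask & D[cbind(i, j)] <= profile$max_ca),
    decoys     = pools((ktsy[i] | ktsy[j]) & inter_mask &
                         D[cbind(i, j)] > profile$max_ca))
  for (ch in chain_ids(s)) {
    m <- tab$chain[i] == ch & tab$chain[j] == ch
    scopes[[paste0("intra:", ch)]] <- list(
      candidates = pools(eligible & m & D[cbind(i, j)] <= profile$max_ca),
      decoys     = pools((ktsy[i] | ktsy[j]) & m &
                           D[cbind(i, j)] > profile$max_ca))
  }
  chain_len <- vapply(chain_ids(s), function(ch) chain_length(s, ch),
                      integer(1))
  structure(list(digest = digest, sasa = sasa, profile = profile,
                 scopes = scopes, chain_lengths = chain_len),
            class = "xl_prep")
}

#' Enumerate crosslink candidate pairs
#'
#' All unordered residue pairs where one residue is crosslinkable on side 1
#' and the other on side 2 of the profile, the CA-CA distance does not
#' exceed the crosslinker bound, and the chain relation matches `scope`.
#' Output is in canonical order (chain id, then residue number).
#'
#' @param s An `xl_structure`.
#' @param profile A [crosslinker_profile()].
#' @param scope `"inter"`, `"intra"`, or `"both"`.
#' @param prep Optional precomputed [xl_prep()].
#' @return data.frame `chain1`, `res1`, `chain2`, `res2`, `dist`.
#' @export
enumerate_candidates <- function(s, profile, scope = c("both", "inter",
                                                       "intra"),
                                 prep = NULL) {
  scope <- match.arg(scope)
  if (is.null(prep)) prep <- xl_prep(s, profile)
  nm <- names(prep$scopes)
  use <- switch(scope,
                inter = "inter",
                intra = grep("^intra:", nm, value = TRUE),
                both  = nm)
  out <- do.call(rbind, lapply(prep$scopes[use], `[[`, "candidates"))
  out <- out[order(out$chain1, out$res1, out$chain2, out$res2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample true crosslinks to the target sequence coverage
#'
#' Draws `n_true = round(coverage * L)` candidates uniformly without
#' replacement (capped at the pool size), where `L` is the length of the
#' longest chain in the candidates' scope — the convention that coverage is
#' sequence coverage of the longer sequence.
#'
#' @param candidates Candidate pool from [enumerate_candidates()].
#' @param s Source `xl_structure` (supplies chain lengths).
#' @param params An [simulation_params()]; uses `coverage` and `seed`.
#' @param longest Override for `L`; defaults to the longest chain among
#'   chains appearing in `candidates`.
#' @return data.frame of links with `is_decoy = FALSE`.
#' @export
sample_true_links <- function(candidates, s, params, longest = NULL) {
  if (is.null(longest)) {
    ch <- unique(c(candidates$chain1, candidates$chain2))
    if (length(ch) == 0L) ch <- chain_ids(s)
    longest <- max(vapply(ch, function(c) chain_length(s, c), integer(1)))
  }
  n_true <- min(round(params$coverage * longest), nrow(candidates))
  if (n_true == 0L) {
    warning("coverage yields zero true links")
    return(empty_links())
  }
  idx <- with_seed(params$seed, sample.int(nrow(candidates), n_true))
  out <- candidates[idx, c("chain1", "res1", "chain2", "res2"), drop = FALSE]
  out$is_decoy <- FALSE
  out$link_fdr <- NA_real_
  rownames(out) <- NULL
  out
}

#' Inject FDR-controlled decoy crosslinks
#'
#' Adds `n_decoy = max(1, round(n_true * fdr / (1 - fdr)))` incorrect links
#' so that decoys/total equals the target FDR, with a floor of one decoy
#' (at least one crosslink is always incorrect). Decoys are drawn uniformly
#' from residue pairs whose CA-CA distance exceeds the crosslinker bound
#' and that contain at least one Lys/Ser/Thr/Tyr, excluding existing links;
#' the combined set is then shuffled.
#'
#' @param true_links Links from [sample_true_links()].
#' @param s Source `xl_structure`.
#' @param profile A [crosslinker_profile()].
#' @param params An [simulation_params()]; uses `fdr` and `seed`.
#' @param scope Scope whose decoy pool to use when `prep` is computed here.
#' @param decoy_pool Optional explicit decoy pool (data.frame like the
#'   candidate pool); overrides `scope`.
#' @param prep Optional precomputed [xl_prep()].
#' @return An `xl_crosslink_set`.
#' @export
inject_noise <- function(true_links, s, profile, params,
                         scope = c("both", "inter", "intra"),
                         decoy_pool = NULL, prep = NULL) {
  if (is.null(decoy_pool)) {
    scope <- match.arg(scope)
    if (is.null(prep)) prep <- xl_prep(s, profile)
    nm <- names(prep$scopes)
    use <- switch(scope,
                  inter = "inter",
                  intra = grep("^intra:", nm, value = TRUE),
                  both  = nm)
    decoy_pool <- do.call(rbind, lapply(prep$scopes[use], `[[`, "decoys"))
  }
  pkey <- paste(decoy_pool$chain1, decoy_pool$res1,
                decoy_pool$chain2, decoy_pool$res2)
  tkey <- paste(true_links$chain1, true_links$res1,
                true_links$chain2, true_links$res2)
  decoy_pool <- decoy_pool[!pkey %in% tkey, , drop = FALSE]
  n_true  <- nrow(true_links)
  n_decoy <- max(1L, round(n_true * params$fdr / (1 - params$fdr)))
  if (nrow(decoy_pool) < n_decoy)
    stop("decoy universe too small (", nrow(decoy_pool), " pairs) to ",
         "honour FDR ", params$fdr, " with ", n_true, " true links")
  links <- with_seed(params$seed, {
    idx <- sample.int(nrow(decoy_pool), n_decoy)
    dec <- decoy_pool[idx, c("chain1", "res1", "chain2", "res2"),
                      drop = FALSE]
    dec$is_decoy <- TRUE
    dec$link_fdr <- NA_real_
    all <- rbind(true_links, dec)
    all[sample.int(nrow(all)), , drop = FALSE]
  })
  new_crosslink_set(links, params)
}

#' Annotate link-level FDR by the shuffle-and-count rule
#'
#' Shuffles the links and assigns to the link at position `i` the fraction
#' of incorrect links observed among positions `1..i` — the running decoy
#' count divided by the position. The shuffled order is retained in the
#' output.
#'
#' @param xs An `xl_crosslink_set` with decoy flags set.
#' @param seed Integer seed for the shuffle.
#' @return The annotated `xl_crosslink_set`.
#' @export
annotate_link_fdr <- function(xs, seed) {
  links <- xs$links
  if (nrow(links) == 0L) return(xs)
  links <- with_seed(seed, links[sample.int(nrow(links)), , drop = FALSE])
  links$link_fdr <- cumsum(links$is_decoy) / seq_len(nrow(links))
  new_crosslink_set(links, xs$params, xs$source)
}

#' Simulate a crosslink set from a structure
#'
#' Full pipeline: enumerate candidates, subsample to coverage, inject
#' FDR-controlled decoys and annotate link-level FDR — run independently
#' for the inter-chain scope and for each chain's intra scope, then
#' concatenated. The result is fully determined by the structure, the
#' crosslinker profile and the parameters (including the seed).
#'
#' @param s An `xl_structure`.
#' @param profile A [crosslinker_profile()].
#' @param params An [simulation_params()].
#' @param prep Optional precomputed [xl_prep()] (performance only).
#' @param source Label recorded in the output set.
#' @return An `xl_crosslink_set`.
#' @export
simulate_crosslinks <- function(s, profile, params = simulation_params(),
                                prep = NULL, source = "structure") {
  if (is.null(prep)) prep <- xl_prep(s, profile)
  nm <- names(prep$scopes)
  use <- switch(params$scope,
                inter = "inter",
                intra = grep("^intra:", nm, value = TRUE),
                both  = nm)
  all_links <- empty_links()
  for (k in seq_along(use)) {
    sc <- use[k]
    base <- (params$seed + (match(sc, nm) - 1L) * 7919L) %%
      .Machine$integer.max
    cand <- prep$scopes[[sc]]$candidates
    ch <- if (sc == "inter") chain_ids(s) else sub("^intra:", "", sc)
    longest <- max(prep$chain_lengths[ch])
    p_samp <- params; p_samp$seed <- base
    true <- if (nrow(cand))
      sample_true_links(cand, s, p_samp, longest = longest)
    else empty_links()
    p_inj <- params; p_inj$seed <- base + 1L
    set <- inject_noise(true, s, profile, p_inj,
                        decoy_pool = prep$scopes[[sc]]$decoys)
    set <- annotate_link_fdr(set, seed = base + 2L)
    all_links <- rbind(all_links, set$links)
  }
  new_crosslink_set(all_links, params, source)
}
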