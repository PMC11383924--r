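# Shared fixtures, memoised so SASA-heavy preparation runs once per suite.
.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

sda <- function() crosslinker_profile("SDA")

small_complex <- function()
  fx_memo("small_complex",
          make_two_chain_complex(fixture_sequence(60), fixture_sequence(50)))

small_prep <- function()
  fx_memo("small_prep", xl_prep(small_complex(), sda()))

big_complex <- function()
  fx_memo("big_complex",
          make_two_chain_complex(fixture_sequence(300), fixture_sequence(250)))

big_prep <- function()
  fx_memo("big_prep", xl_prep(big_complex(), sda()))

# Single-residue, single-atom structures for analytic SASA / distance cases.
point_structure <- function(coords, chain = "A", elety = "CA",
                            element = "C", resid = "ALA") {
  n <- nrow(coords)
  xl_structure(data.frame(
    chain = rep_len(chain, n), resno = seq_len(n),
    resid = rep_len(resid, n), elety = rep_len(elety, n),
    element = rep_len(element, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE))
}

# Vectorised CA-CA distances of a link table in a structure.
link_distances <- function(s, links) {
  tab <- do.call(rbind, lapply(chain_ids(s), function(ch) {
    m <- ca_matrix(s, ch)
    data.frame(key = paste(ch, rownames(m)), x = m[, 1], y = m[, 2],
               z = m[, 3], stringsAsFactors = FALSE)
  }))
  i <- match(paste(links$chain1, links$res1), tab$key)
  j <- match(paste(links$chain2, links$res2), tab$key)
  sqrt((tab$x[i] - tab$x[j])^2 + (tab$y[i] - tab$y[j])^2 +
         (tab$z[i] - tab$z[j])^2)
}

random_aa_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
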