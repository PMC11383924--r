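backbone_atoms <- c("N", "CA", "C", "O")

# Backbone coordinate rows keyed by chain|resno|atom for matched selection.
backbone_table <- function(s, chain, resnos = NULL) {
  a <- s$atoms[s$atoms$chain == chain & s$atoms$elety %in% backbone_atoms, ,
               drop = FALSE]
  if (!is.null(resnos)) a <- a[a$resno %in% resnos, , drop = FALSE]
  a$key <- paste(a$chain, a$resno, a$elety, sep = "|")
  a
}

# Matched native/model coordinate matrices over common backbone atoms.
matched_backbone <- function(native, model, sel) {
  nat <- do.call(rbind, lapply(seq_along(sel), function(i)
    backbone_table(native, names(sel)[i], sel[[i]])))
  mod <- do.call(rbind, lapply(seq_along(sel), function(i)
    backbone_table(model, names(sel)[i], sel[[i]])))
  common <- intersect(nat$key, mod$key)
  if (length(common) < 3L)
    stop("fewer than 3 matched backbone atoms between native and model")
  nat <- nat[match(common, nat$key), c("x", "y", "z")]
  mod <- mod[match(common, mod$key), c("x", "y", "z")]
  list(native = as.matrix(nat), model = as.matrix(mod),
       n_atoms = length(common))
}

#' Inter-chain residue contacts
#'
#' Residue pairs from two different chains with at least one heavy-atom
#' (non-hydrogen) pair within `cutoff` Angstrom.
#'
#' @param s An `xl_structure`.
#' @param chain_a,chain_b Chain ids.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (contacts: 5;
#'   interface definition for iRMS: 10).
#' @return data.frame `res_a`, `res_b` (author numbers), canonically
#'   ordered; zero rows when there is no contact.
#' @export
interface_contacts <- function(s, chain_a, chain_b, cutoff = 5) {
  heavy <- function(ch) {
    a <- s$atoms[s$atoms$chain == ch & !(s$atoms$element %in% c("H", "D")), ,
                 drop = FALSE]
    if (nrow(a) == 0L) stop("unknown or empty chain: ", ch)
    a
  }
  A <- heavy(chain_a); B <- heavy(chain_b)
  xa <- as.matrix(A[, c("x", "y", "z")])
  xb <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(res_a = integer(), res_b = integer()))
  pairs <- unique(data.frame(res_a = A$resno[hit[, 1]],
                             res_b = B$resno[hit[, 2]]))
  pairs <- pairs[order(pairs$res_a, pairs$res_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Fraction of native contacts recovered by a model
#'
#' Recall of the native cross-chain residue contacts (heavy atoms within
#' 5 Angstrom) in the model interface. Returns 0 (with a message) when the
#' native interface has no contacts.
#'
#' @param native,model `xl_structure`s with corresponding chain ids.
#' @param chain_a,chain_b Chain ids of the interface.
#' @param cutoff Contact cutoff in Angstrom.
#' @return Fraction in [0, 1].
#' @export
fnat <- function(native, model, chain_a, chain_b, cutoff = 5) {
  nat <- interface_contacts(native, chain_a, chain_b, cutoff)
  if (nrow(nat) == 0L) {
    message("native interface ", chain_a, "-", chain_b, " has no contacts")
    return(0)
  }
  mod <- interface_contacts(model, chain_a, chain_b, cutoff)
  mean(paste(nat$res_a, nat$res_b) %in% paste(mod$res_a, mod$res_b))
}

#' Interface RMSD
#'
#' Backbone (N, CA, C, O) RMSD over the interface residues — native
#' contacts at the widened 10 Angstrom cutoff — after least-squares
#' superposition of the model interface onto the native interface.
#'
#' @inheritParams fnat
#' @param interface_cutoff Interface definition cutoff in Angstrom.
#' @return RMSD in Angstrom.
#' @export
irms <- function(native, model, chain_a, chain_b, interface_cutoff = 10) {
  ic <- interface_contacts(native, chain_a, chain_b, interface_cutoff)
  if (nrow(ic) == 0L)
    stop("no native interface between ", chain_a, " and ", chain_b,
         " at ", interface_cutoff, " A")
  sel <- list(unique(ic$res_a), unique(ic$res_b))
  names(sel) <- c(chain_a, chain_b)
  mb <- matched_backbone(native, model, sel)
  superpose(mb$model, mb$native)$rmsd
}

#' Ligand RMSD
#'
#' Superposes the model onto the native on the backbone of the larger
#' chain (by residue count) and reports the backbone RMSD of the smaller
#' chain.
#'
#' @inheritParams fnat
#' @return RMSD in Angstrom.
#' @export
lrms <- function(native, model, chain_a, chain_b) {
  na <- chain_length(native, chain_a)
  nb <- chain_length(native, chain_b)
  larger  <- if (nb > na) chain_b else chain_a
  smaller <- if (nb > na) chain_a else chain_b
  sel_l <- stats::setNames(list(NULL), larger)
  sel_s <- stats::setNames(list(NULL), smaller)
  big   <- matched_backbone(native, model, sel_l)
  small <- matched_backbone(native, model, sel_s)
  tf <- superpose(big$model, big$native)
  fit <- apply_transform(small$model, tf)
  sqrt(mean(rowSums((fit - small$native)^2)))
}

#' CAPRI-style quality class of a DockQ score
#'
#' Thresholds: below 0.23 incorrect; 0.23 up to and including 0.49
#' acceptable; above 0.49 and below 0.8 medium; 0.8 and above high.
#'
#' @param score Numeric vector of DockQ scores.
#' @return Character vector of classes.
#' @export
classify_dockq <- function(score) {
  ifelse(score < 0.23, "incorrect",
         ifelse(score <= 0.49, "acceptable",
                ifelse(score < 0.8, "medium", "high")))
}

#' DockQ interface-quality score
#'
#' For each native-contacting chain pair shared by native and model,
#' computes the fraction of native contacts (Fnat, 5 Angstrom heavy-atom
#' cutoff), the interface RMSD (iRMS, interface at 10 Angstrom) and the
#' ligand RMSD (LRMS), and combines them as
#' `(Fnat + 1/(1+(iRMS/1.5)^2) + 1/(1+(LRMS/8.5)^2)) / 3`.
#' For complexes with more than two chains the final score is the average
#' over all native interfaces; chain pairs without native contacts are
#' skipped. Chain correspondence is by id.
#'
#' @param native,model `xl_structure`s.
#' @return An `xl_dockq`: list with `fnat`, `irms`, `lrms`, `dockq`
#'   (interface means), `quality`, and `per_interface` (one row per chain
#'   pair).
#' @export
dockq <- function(native, model) {
  shared <- intersect(chain_ids(native), chain_ids(model))
  if (length(shared) < 2L)
    stop("native and model share fewer than 2 chains")
  pairs <- utils::combn(shared, 2, simplify = FALSE)
  per <- lapply(pairs, function(p) {
    nat_contacts <- interface_contacts(native, p[1], p[2], 5)
    if (nrow(nat_contacts) == 0L) return(NULL)
    fn <- fnat(native, model, p[1], p[2])
    ir <- irms(native, model, p[1], p[2])
    lr <- lrms(native, model, p[1], p[2])
    dq <- (fn + 1 / (1 + (ir / 1.5)^2) + 1 / (1 + (lr / 8.5)^2)) / 3
    data.frame(chain_a = p[1], chain_b = p[2], fnat = fn, irms = ir,
               lrms = lr, dockq = dq, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0L)
    stop("no native interface found between shared chains")
  score <- mean(per$dockq)
  structure(list(fnat = mean(per$fnat), irms = mean(per$irms),
                 lrms = mean(per$lrms), dockq = score,
                 quality = classify_dockq(score), per_interface = per),
            class = "xl_dockq")
}

#' @export
print.xl_dockq <- function(x, ...) {
  cat(sprintf(
    "xl_dockq: DockQ %.3f (%s)  Fnat %.3f  iRMS %.2f A  LRMS %.2f A  [%d interface(s)]\n",
    x$dockq, x$quality, x$fnat, x$irms, x$lrms, nrow(x$per_interface)))
  invisible(x)
}
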