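# Pedigree breed-fraction propagation through crossing schemes, in exact
# rational arithmetic.

#' Expected breed fractions along a crossing scheme
#'
#' Propagates founder-breed fractions through a directed mating graph:
#' founders carry a unit fraction of their own breed and every cross's
#' fractions are the exact arithmetic mean of its parents' (rational
#' arithmetic, no floating point).  The scheme is a data.frame with
#' columns `node`, `sire`, `dam`; founders have `NA` parents and their
#' `node` names the breed, and parent references must point to
#' earlier-declared nodes or breed names (a cycle is therefore
#' impossible to declare and is rejected).
#'
#' @param scheme scheme data.frame (see above, or [canchim_scheme()]).
#' @param breeds optional breed universe; defaults to the founder names.
#' @return list with `fractions` (nodes-by-breeds numeric matrix) and
#'   `exact` (same shape, fractions as strings like `"5/8"`).
#' @examples
#' ped <- pedigree_expected_fraction(canchim_scheme())
#' ped$exact["CA", ]   # 5/8 CH, 3/8 ZB
#' ped$exact["MA", ]   # 21/32 CH
#' @export
pedigree_expected_fraction <- function(scheme, breeds = NULL) {
  scheme <- as.data.frame(scheme, stringsAsFactors = FALSE)
  .stop_if(!all(c("node", "sire", "dam") %in% names(scheme)),
           "scheme needs columns node, sire, dam")
  founders <- scheme$node[is.na(scheme$sire) & is.na(scheme$dam)]
  refs <- stats::na.omit(c(scheme$sire, scheme$dam))
  implicit <- setdiff(refs, scheme$node)
  if (is.null(breeds)) breeds <- unique(c(founders, implicit))
  .stop_if(length(breeds) == 0, "scheme has no founder breeds")
  # fractions as rational numbers: per node, a list of (num, den) per breed
  frac <- list()
  unit <- function(breed) {
    lapply(breeds, function(b) .rat(as.integer(b == breed)))
  }
  get_frac <- function(name, node_of) {
    if (!is.null(frac[[name]])) return(frac[[name]])
    .stop_if(!(name %in% breeds),
             sprintf("parent '%s' of node '%s' is neither an earlier node nor a breed (cycle or missing parent)",
                     name, node_of))
    unit(name)
  }
  for (r in seq_len(nrow(scheme))) {
    nd <- scheme$node[r]
    .stop_if(!is.null(frac[[nd]]), sprintf("node '%s' declared twice", nd))
    if (is.na(scheme$sire[r]) && is.na(scheme$dam[r])) {
      .stop_if(!(nd %in% breeds),
               sprintf("founder '%s' must name a breed", nd))
      frac[[nd]] <- unit(nd)
    } else {
      .stop_if(is.na(scheme$sire[r]) || is.na(scheme$dam[r]),
               sprintf("node '%s' must have two parents or none", nd))
      s <- get_frac(scheme$sire[r], nd)
      d <- get_frac(scheme$dam[r], nd)
      frac[[nd]] <- lapply(seq_along(breeds), function(b)
        .rat_halve(.rat_add(s[[b]], d[[b]])))
    }
  }
  nodes <- scheme$node
  num <- t(vapply(nodes, function(nd)
    vapply(frac[[nd]], function(x) x["num"] / x["den"], numeric(1)),
    numeric(length(breeds))))
  ex <- t(vapply(nodes, function(nd)
    vapply(frac[[nd]], .rat_format, character(1)),
    character(length(breeds))))
  dimnames(num) <- dimnames(ex) <- list(nodes, breeds)
  list(fractions = num, exact = ex)
}

#' The Canchim crossing design
#'
#' Built-in mating graph of the crossing schemes that form the Canchim
#' composite breed and its genetic groups from Charolais (CH) and Zebu
#' (ZB) founders: three backcross generations ending in the inter se CA
#' cross (5/8 CH), the MA group (Charolais bull on a 1/2 Canchim + 1/2
#' Zebu dam, 21/32 CH), and the scheme-IV products C2 (CA x MA) and C3
#' (MA x MA).
#'
#' @return a scheme data.frame usable with
#'   [pedigree_expected_fraction()] and [simulate_crossing_scheme()].
#' @export
canchim_scheme <- function() {
  data.frame(
    node = c("CH", "ZB", "F1", "BC1", "BC2", "CA", "MAdam", "MA",
             "C2", "C3"),
    sire = c(NA, NA, "CH", "ZB", "CH", "BC2", "CA", "CH", "CA", "MA"),
    dam  = c(NA, NA, "ZB", "F1", "BC1", "BC2", "ZB", "MAdam", "MA", "MA"),
    stringsAsFactors = FALSE)
}
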