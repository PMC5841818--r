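#' Load a compartmentalized metabolic network definition
#'
#' Reads a network-definition JSON file (species with concentration bounds
#' and resting concentrations, reactions with signed stoichiometries,
#' standard transformed reaction free energies, pathway tags) and returns a
#' validated `metabolic_network` object. The canonical packaged network
#' describes glucose and palmitate catabolism in exercising skeletal muscle:
#' glycolysis, the lactate branch, the glycerol-3-phosphate shuttle,
#' pyruvate oxidation, the TCA cycle, fatty-acid activation and carnitine
#' transport, the full C16-to-C4 beta-oxidation spiral, acyl-carnitine side
#' pools, oxidative phosphorylation with a proton-motive pseudo-species, and
#' bioenergetic demand/buffer reactions.
#'
#' Validation enforces: three compartments with volume fractions summing
#' to 1; unique species ids with compartment-consistent `_e`/`_m` suffixes;
#' positive concentration bounds with `lb <= conc <= ub`; declared species
#' for every stoichiometric entry; and exact carbon conservation for every
#' non-boundary reaction (cofactor moieties carry zero carbon by the file's
#' stated convention).
#'
#' @param path path to a network-definition JSON file.
#' @return an object of class `metabolic_network` with elements
#'   `species` (data.frame), `reactions` (list), `S` (dense signed
#'   integer matrix, species x reactions), `compartments` (data.frame),
#'   and `water_volume_l_per_kg`.
#' @seealso [canonical_network()], [stoichiometric_matrix()],
#'   [pathway_members()]
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (fld in c("compartments", "species", "reactions"))
    if (is.null(raw[[fld]])) stop("network schema error: missing '", fld, "' block")

  comp <- data.frame(
    id = vapply(raw$compartments, function(x) x$id, ""),
    volume_fraction = vapply(raw$compartments, function(x) as.numeric(x$volume_fraction), 0),
    stringsAsFactors = FALSE
  )
  if (nrow(comp) != 3L ||
      !setequal(comp$id, c("extracellular", "cytosol", "mitochondrion")))
    stop("network validation error: exactly the three canonical compartments are required")
  if (abs(sum(comp$volume_fraction) - 1) > 1e-12)
    stop("network validation error: compartment volume fractions must sum to 1")

  species <- data.frame(
    id = vapply(raw$species, function(x) x$id, ""),
    name = vapply(raw$species, function(x) x$name, ""),
    compartment = vapply(raw$species, function(x) x$compartment, ""),
    carbon = vapply(raw$species, function(x) as.numeric(x$carbon), 0),
    lb = vapply(raw$species, function(x) as.numeric(x$lb), 0),
    ub = vapply(raw$species, function(x) as.numeric(x$ub), 0),
    conc = vapply(raw$species, function(x) as.numeric(x$conc), 0),
    volume_scale = vapply(raw$species, function(x)
      if (is.null(x$volume_scale)) 1 else as.numeric(x$volume_scale), 0),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(species$id))
    stop("network validation error: duplicate species ids: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  if (!all(species$compartment %in% comp$id))
    stop("network schema error: species reference unknown compartments")
  suffix_ok <- ifelse(species$compartment == "extracellular", endsWith(species$id, "_e"),
               ifelse(species$compartment == "mitochondrion", endsWith(species$id, "_m"),
                      !endsWith(species$id, "_e") & !endsWith(species$id, "_m")))
  if (!all(suffix_ok))
    stop("network validation error: species id suffix inconsistent with compartment: ",
         paste(species$id[!suffix_ok], collapse = ", "))
  bad_bounds <- species$lb <= 0 | species$lb > species$ub |
    species$conc < species$lb | species$conc > species$ub
  if (any(bad_bounds))
    stop("network validation error: concentration bounds violated for: ",
         paste(species$id[bad_bounds], collapse = ", "))
  if (any(species$carbon < 0 | species$carbon != round(species$carbon)))
    stop("network validation error: carbon counts must be non-negative integers")

  reactions <- lapply(raw$reactions, function(x) {
    st <- vapply(x$stoich, as.numeric, 0)
    list(id = x$id, name = x$name, stoich = st,
         dg0 = as.numeric(x$dg0), pathway = x$pathway,
         boundary = isTRUE(x$boundary), reversible = isTRUE(x$reversible))
  })
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("network validation error: duplicate reaction ids")
  tags <- vapply(reactions, `[[`, "", "pathway")
  bad_tag <- !tags %in% pathway_tags()
  if (any(bad_tag))
    stop("network schema error: unknown pathway tag(s): ",
         paste(unique(tags[bad_tag]), collapse = ", "))

  for (r in reactions) {
    missing <- setdiff(names(r$stoich), species$id)
    if (length(missing))
      stop("network schema error: reaction ", r$id,
           " references undeclared species: ", paste(missing, collapse = ", "))
    if (any(r$stoich == 0 | r$stoich != round(r$stoich)))
      stop("network validation error: reaction ", r$id,
           " has non-integer or zero stoichiometric coefficients")
  }

  S <- matrix(0, nrow(species), length(reactions),
              dimnames = list(species$id, rids))
  for (k in seq_along(reactions))
    S[names(reactions[[k]]$stoich), k] <- reactions[[k]]$stoich

  carbon <- setNames(species$carbon, species$id)
  for (k in seq_along(reactions)) {
    if (reactions[[k]]$boundary) next
    bal <- sum(S[, k] * carbon)
    if (abs(bal) > 1e-9)
      stop("network validation error: carbon imbalance in reaction ",
           rids[k], " (net carbon ", bal, ")")
  }
  orphans <- rownames(S)[rowSums(S != 0) == 0]
  if (length(orphans))
    stop("network validation error: orphan species: ",
         paste(orphans, collapse = ", "))

  structure(list(
    name = if (!is.null(raw$name)) raw$name else basename(path),
    species = species,
    reactions = reactions,
    reaction_ids = rids,
    S = S,
    compartments = comp,
    water_volume_l_per_kg =
      if (!is.null(raw$water_volume_l_per_kg)) as.numeric(raw$water_volume_l_per_kg) else 0.755
  ), class = "metabolic_network")
}

#' The canonical packaged fuel-selection network
#'
#' Loads the packaged 98-species / 87-reaction skeletal-muscle network.
#' @return a `metabolic_network`.
#' @export
canonical_network <- function() {
  load_network(system.file("extdata", "network_canonical.json",
                           package = "fuelswitch", mustWork = TRUE))
}

#' Valid pathway tags
#' @return character vector of the recognized pathway tags.
#' @export
pathway_tags <- function() {
  c("glycolysis", "lactate", "g3p_shuttle", "pyruvate", "tca",
    "fa_activation_transport", "beta_oxidation", "carnitine_handling",
    "oxphos", "bioenergetics", "exchange")
}

#' Stoichiometric matrix of a network
#'
#' @param net a `metabolic_network`.
#' @return dense signed integer matrix (species rows in network order,
#'   reaction columns in network order).
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  net$S
}

#' Reactions carrying a pathway tag
#'
#' @param net a `metabolic_network`.
#' @param tag one of [pathway_tags()].
#' @return character vector of reaction ids.
#' @export
pathway_members <- function(net, tag) {
  stopifnot(inherits(net, "metabolic_network"))
  if (length(tag) != 1L || !tag %in% pathway_tags())
    stop("unknown pathway tag: ", paste(tag, collapse = ", "))
  net$reaction_ids[vapply(net$reactions, `[[`, "", "pathway") == tag]
}

#' Reaction subsets used by the genotype hypotheses
#'
#' `mito_reactions()` returns the "total mitochondrial activity" set (tags:
#' pyruvate, tca, beta_oxidation, carnitine_handling, oxphos, and
#' fa_activation_transport — the mitochondrially housed machinery scaled by
#' mitochondrial density). `fa_transport_reactions()` returns the fatty-acid
#' activation/transport set and `fao_reactions()` the transport set plus the
#' beta-oxidation spiral.
#' @param net a `metabolic_network`.
#' @return character vector of reaction ids.
#' @export
mito_reactions <- function(net) {
  tags <- c("pyruvate", "tca", "beta_oxidation", "carnitine_handling",
            "oxphos", "fa_activation_transport")
  unlist(lapply(tags, pathway_members, net = net), use.names = FALSE)
}

#' @rdname mito_reactions
#' @export
fa_transport_reactions <- function(net) pathway_members(net, "fa_activation_transport")

#' @rdname mito_reactions
#' @export
fao_reactions <- function(net)
  c(pathway_members(net, "fa_activation_transport"),
    pathway_members(net, "beta_oxidation"))

#' Exchange (boundary) reactions
#' @param net a `metabolic_network`.
#' @return character vector of the boundary reaction ids.
#' @export
exchange_reactions <- function(net)
  net$reaction_ids[vapply(net$reactions, `[[`, TRUE, "boundary")]

#' Serialize a network back to its JSON definition format
#'
#' Writes a file that [load_network()] reads back to an identical network
#' (id-for-id, coefficient-for-coefficient round trip).
#' @param net a `metabolic_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  out <- list(
    name = net$name,
    water_volume_l_per_kg = net$water_volume_l_per_kg,
    compartments = lapply(seq_len(nrow(net$compartments)), function(i)
      list(id = net$compartments$id[i],
           volume_fraction = net$compartments$volume_fraction[i])),
    species = lapply(seq_len(nrow(net$species)), function(i)
      list(id = net$species$id[i], name = net$species$name[i],
           compartment = net$species$compartment[i],
           carbon = net$species$carbon[i], lb = net$species$lb[i],
           ub = net$species$ub[i], conc = net$species$conc[i],
           volume_scale = net$species$volume_scale[i])),
    reactions = lapply(net$reactions, function(r)
      list(id = r$id, name = r$name, stoich = as.list(r$stoich),
           dg0 = r$dg0, pathway = r$pathway, boundary = r$boundary,
           reversible = r$reversible))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resting concentration vector packaged with a network
#' @param net a `metabolic_network`.
#' @return named numeric vector (molar), in species order.
#' @export
resting_concentrations <- function(net)
  setNames(net$species$conc, net$species$id)

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$name, "\n", sep = "")
  cat("  ", nrow(x$species), " species, ", length(x$reactions),
      " reactions (", length(exchange_reactions(x)), " exchanges)\n", sep = "")
  tab <- table(vapply(x$reactions, `[[`, "", "pathway"))
  cat("  pathways: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}
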