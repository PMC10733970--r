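## Neuron geometry: SWC reading, reduced species presets, discretization,
## distance-dependent conductance distributions, synapse-site eligibility.
##
## A morphology is a tree of sections (soma root). Path distances are
## measured from the soma center to the compartment midpoint, in um; the
## soma itself contributes zero length.

.REGIONS <- c("soma", "axon", "basal", "apical_trunk", "oblique")

.new_morphology <- function(sections) {
  rownames(sections) <- NULL
  structure(list(sections = sections), class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  s <- x$sections
  cat(sprintf("morphology: %d sections, total length %.0f um\n",
              nrow(s), sum(s$length_um[s$region != "soma"])))
  print(table(s$region))
  invisible(x)
}

.validate_sections <- function(sections) {
  need <- c("name", "region", "parent", "parent_pos", "length_um",
            "diam_prox_um", "diam_dist_um")
  stopifnot(all(need %in% names(sections)))
  if (sum(is.na(sections$parent)) != 1L)
    stop("morphology must have exactly one root (the soma)")
  if (sections$region[is.na(sections$parent)] != "soma")
    stop("the root section must be the soma")
  if (any(sections$length_um <= 0) ||
      any(sections$diam_prox_um <= 0) || any(sections$diam_dist_um <= 0))
    stop("section lengths and diameters must be positive")
  if (!all(sections$region %in% .REGIONS))
    stop("unknown region label")
  ## acyclic + reachable: parents must precede children
  idx <- match(sections$parent, sections$name)
  if (any(!is.na(sections$parent) & is.na(idx)))
    stop("section parent not found")
  if (any(which(!is.na(idx)) <= idx[!is.na(idx)]))
    stop("sections must be ordered parent-before-child")
  sections
}

## ---- SWC ------------------------------------------------------------------

#' Read an SWC morphology file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent). Types 1-4 map
#' to soma/axon/basal/apical; all soma samples collapse into a single root
#' section. Within the apical tree, the maximal-diameter path from the apical
#' root is labeled `apical_trunk` and branches off it `oblique`.
#'
#' @param path SWC file path.
#' @return A `morphology` object.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty SWC file")
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) != 7) stop("SWC must have 7 columns")
  colnames(m) <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (any(m[, "radius"] <= 0)) stop("non-positive radius in SWC")
  roots <- m[, "parent"] == -1
  if (sum(roots) != 1) stop("SWC must have exactly one root")
  ## forward references are parse errors
  pos <- match(m[, "parent"], m[, "id"])
  bad <- !roots & (is.na(pos) | pos >= seq_len(nrow(m)))
  if (any(bad)) stop("SWC parent id references a missing or later line")

  soma_ids <- m[m[, "type"] == 1, "id"]
  if (!length(soma_ids)) stop("SWC has no soma (type 1) sample")
  soma_diam <- 2 * m[m[, "id"] == soma_ids[1], "radius"]

  region_of <- function(type) switch(as.character(type),
    "2" = "axon", "3" = "basal", "4" = "apical", "apical")

  ## each non-soma sample becomes one frustum section from its parent sample
  rows <- list(data.frame(name = "soma", region = "soma", parent = NA,
                          parent_pos = 0.5, length_um = soma_diam,
                          diam_prox_um = soma_diam, diam_dist_um = soma_diam,
                          stringsAsFactors = FALSE))
  sec_name <- stats::setNames(rep("soma", length(soma_ids)), soma_ids)
  for (k in seq_len(nrow(m))) {
    row <- m[k, ]
    if (row["type"] == 1) next
    pid <- row["parent"]
    prow <- m[m[, "id"] == pid, , drop = FALSE]
    len <- sqrt(sum((row[c("x", "y", "z")] - prow[1, c("x", "y", "z")])^2))
    if (len <= 0) len <- 0.1
    pname <- sec_name[[as.character(pid)]]
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("swc_", row["id"]), region = region_of(row["type"]),
      parent = pname, parent_pos = if (pname == "soma") 0.5 else 1,
      length_um = len,
      diam_prox_um = if (prow[1, "type"] == 1) 2 * row["radius"]
                     else 2 * prow[1, "radius"],
      diam_dist_um = 2 * row["radius"], stringsAsFactors = FALSE)
    sec_name[[as.character(row["id"])]] <- paste0("swc_", row["id"])
  }
  sections <- do.call(rbind, rows)
  sections <- .label_apical(sections)
  .new_morphology(.validate_sections(sections))
}

## apical trunk = maximal-diameter path from the apical root; everything
## else in the apical tree is an oblique
.label_apical <- function(sections) {
  api <- which(sections$region == "apical")
  if (!length(api)) return(sections)
  children <- split(seq_len(nrow(sections)), sections$parent)
  trunk <- integer(0)
  start <- api[sections$parent[api] == "soma" |
               !(sections$parent[api] %in% sections$name[api])]
  if (!length(start)) start <- api[1]
  cur <- start[which.max(sections$diam_dist_um[start])]
  while (length(cur)) {
    trunk <- c(trunk, cur)
    kids <- children[[sections$name[cur]]]
    kids <- kids[sections$region[kids] == "apical"]
    cur <- if (length(kids)) kids[which.max(sections$diam_dist_um[kids])]
           else integer(0)
  }
  sections$region[api] <- "oblique"
  sections$region[trunk] <- "apical_trunk"
  sections
}

#' Write a morphology to SWC
#'
#' Lossy on 3D layout (sections are laid out along abstract axes) but
#' geometry (lengths, diameters, topology) round-trips.
#' @param m A `morphology`.
#' @param path Output path.
#' @export
write_swc <- function(m, path) {
  s <- m$sections
  id <- 0L
  lines <- character(0)
  tip_id <- stats::setNames(vector("list", nrow(s)), s$name)
  tip_xy <- stats::setNames(vector("list", nrow(s)), s$name)
  type_of <- c(soma = 1, axon = 2, basal = 3, apical_trunk = 4, oblique = 4)
  for (k in seq_len(nrow(s))) {
    if (is.na(s$parent[k])) {
      id <- id + 1L
      lines <- c(lines, sprintf("%d 1 0 0 0 %.6g -1", id, s$diam_prox_um[k] / 2))
      tip_id[[s$name[k]]] <- id
      tip_xy[[s$name[k]]] <- c(0, 0)
    } else {
      pid <- tip_id[[s$parent[k]]]
      p0 <- tip_xy[[s$parent[k]]]
      ## each section follows its own golden-angle direction so branch
      ## points never collide and lengths are preserved exactly
      th <- k * 2.399963
      xy <- p0 + s$length_um[k] * c(cos(th), sin(th))
      id <- id + 1L
      lines <- c(lines, sprintf("%d %d %.6g %.6g 0 %.6g %d", id,
                                type_of[[s$region[k]]], xy[1], xy[2],
                                s$diam_dist_um[k] / 2, pid))
      tip_id[[s$name[k]]] <- id
      tip_xy[[s$name[k]]] <- xy
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- reduced species presets ----------------------------------------------

#' Reduced-morphology geometry preset
#'
#' Desk-scale branched geometries emulating the species trends: the rat
#' preset has a thicker, longer apical trunk and more total dendrite than
#' the mouse preset, hence lower input resistance.
#'
#' @param species `"mouse"` or `"rat"`.
#' @return Named list of geometric parameters for
#'   [build_reduced_morphology()].
#' @export
reduced_morphology_preset <- function(species = c("mouse", "rat")) {
  species <- match.arg(species)
  if (species == "mouse")
    list(soma_L = 18, soma_diam = 18, axon_L = 100, axon_diam = 1,
         trunk_L = 350, trunk_diam0 = 2.2, trunk_diam1 = 0.6,
         oblique_offsets = c(60, 110, 160, 210, 260),
         oblique_L = 120, oblique_diam = 0.75,
         n_basal = 2, basal_L = 150, basal_diam = 1.0)
  else
    list(soma_L = 21, soma_diam = 21, axon_L = 100, axon_diam = 1,
         trunk_L = 450, trunk_diam0 = 3.5, trunk_diam1 = 1.0,
         oblique_offsets = c(60, 120, 180, 240, 300),
         oblique_L = 150, oblique_diam = 1.1,
         n_basal = 2, basal_L = 200, basal_diam = 1.2)
}

#' Build a reduced branched morphology
#'
#' Soma + axon + linearly tapering apical trunk with obliques at stated path
#' offsets + basal sections.
#'
#' @param geom Geometry list from [reduced_morphology_preset()] (or the same
#'   shape with explicit values), or a species name.
#' @return A `morphology` object.
#' @export
build_reduced_morphology <- function(geom = "mouse") {
  if (is.character(geom)) geom <- reduced_morphology_preset(geom)
  g <- geom
  stopifnot(all(unlist(g[c("soma_L", "soma_diam", "axon_L", "trunk_L",
                           "trunk_diam0", "oblique_L",
                           "basal_L")]) > 0))
  rows <- list(
    data.frame(name = "soma", region = "soma", parent = NA, parent_pos = 0.5,
               length_um = g$soma_L, diam_prox_um = g$soma_diam,
               diam_dist_um = g$soma_diam, stringsAsFactors = FALSE),
    data.frame(name = "axon", region = "axon", parent = "soma",
               parent_pos = 0, length_um = g$axon_L,
               diam_prox_um = g$axon_diam, diam_dist_um = g$axon_diam,
               stringsAsFactors = FALSE))
  ## trunk split at oblique attachment points so obliques sit at the stated
  ## path offsets
  offs <- sort(g$oblique_offsets)
  if (any(offs <= 0) || any(offs >= g$trunk_L))
    stop("oblique offsets must lie inside the trunk")
  cuts <- c(0, offs, g$trunk_L)
  diam_at <- function(x) {
    d <- g$trunk_diam0 + (g$trunk_diam1 - g$trunk_diam0) * x / g$trunk_L
    if (d <= 0) stop("trunk taper produces non-positive diameter")
    d
  }
  prev <- "soma"
  for (i in seq_len(length(cuts) - 1L)) {
    nm <- sprintf("trunk_%d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, region = "apical_trunk", parent = prev,
      parent_pos = if (prev == "soma") 1 else 1,
      length_um = cuts[i + 1] - cuts[i],
      diam_prox_um = diam_at(cuts[i]), diam_dist_um = diam_at(cuts[i + 1]),
      stringsAsFactors = FALSE)
    if (i <= length(offs))
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("oblique_%d", i), region = "oblique", parent = nm,
        parent_pos = 1, length_um = g$oblique_L,
        diam_prox_um = g$oblique_diam, diam_dist_um = g$oblique_diam,
        stringsAsFactors = FALSE)
    prev <- nm
  }
  for (b in seq_len(g$n_basal))
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("basal_%d", b), region = "basal", parent = "soma",
      parent_pos = 0, length_um = g$basal_L, diam_prox_um = g$basal_diam,
      diam_dist_um = g$basal_diam, stringsAsFactors = FALSE)
  sections <- do.call(rbind, rows)
  ## keep obliques after their parent trunk pieces but order parent-first
  .new_morphology(.validate_sections(sections))
}

## ---- discretization -------------------------------------------------------

#' Discretize a morphology into compartments
#'
#' Each section is split into an odd number of equal compartments no longer
#' than `max_seg_um`. Path distance is from the soma center to the
#' compartment midpoint.
#'
#' @param m A `morphology`.
#' @param max_seg_um Maximum compartment length (um); default 20.
#' @return Data frame with one row per compartment: section, region, position
#'   along the section, length, midpoint diameter, membrane area (cm2),
#'   axial resistance (MOhm), path distance (um), and parent compartment id.
#' @export
discretize <- function(m, max_seg_um = 20) {
  s <- m$sections
  comps <- list()
  sec_first <- sec_last <- stats::setNames(integer(nrow(s)), s$name)
  sec_dist0 <- stats::setNames(numeric(nrow(s)), s$name) # path dist at 0-end
  id <- 0L
  for (k in seq_len(nrow(s))) {
    L <- s$length_um[k]
    nseg <- max(1L, ceiling(L / max_seg_um))
    if (nseg %% 2L == 0L) nseg <- nseg + 1L
    if (s$region[k] == "soma") nseg <- 1L
    seg_L <- L / nseg
    d0 <- if (is.na(s$parent[k])) 0 else {
      p <- s$parent[k]
      base <- sec_dist0[[p]]
      plen <- s$length_um[match(p, s$name)]
      if (s$region[match(p, s$name)] == "soma") 0
      else base + s$parent_pos[k] * plen
    }
    sec_dist0[[s$name[k]]] <- d0
    for (j in seq_len(nseg)) {
      id <- id + 1L
      mid <- (j - 0.5) / nseg
      diam <- s$diam_prox_um[k] +
        (s$diam_dist_um[k] - s$diam_prox_um[k]) * mid
      if (j == 1L) {
        parent_comp <- if (is.na(s$parent[k])) NA_integer_ else {
          p <- s$parent[k]
          if (s$region[match(p, s$name)] == "soma") sec_first[[p]]
          else sec_last[[p]] # attach at parent distal end (parent_pos 1)
        }
      } else parent_comp <- id - 1L
      comps[[id]] <- data.frame(
        comp = id, section = s$name[k], region = s$region[k], pos = mid,
        length_um = seg_L, diam_um = diam,
        area_cm2 = pi * diam * seg_L * 1e-8,
        ## axial resistance of the full compartment at unit Ra (Ohm*cm):
        ## R = Ra * L / (pi r^2), in MOhm per (Ohm*cm)
        r_axial_unit = seg_L / (pi * (diam / 2)^2) * 1e-2 * 1e-4 * 1e4,
        path_dist_um = if (s$region[k] == "soma") 0 else d0 + mid * L,
        parent_comp = parent_comp, stringsAsFactors = FALSE)
      if (j == 1L) sec_first[[s$name[k]]] <- id
      sec_last[[s$name[k]]] <- id
    }
  }
  out <- do.call(rbind, comps)
  rownames(out) <- NULL
  out
}

## ---- conductance distributions --------------------------------------------

#' Distance-dependent conductance distribution rule
#'
#' Density at path distance `x` is `base` (uniform), `base + slope * x`
#' (linear), or `base + amp / (1 + exp(-(x - midpoint)/steepness))`
#' (sigmoidal), clamped to `[clamp_lo, clamp_hi]`.
#'
#' @param channel Channel name the rule applies to.
#' @param regions Character vector of regions.
#' @param profile `"uniform"`, `"linear_with_distance"`, or
#'   `"sigmoidal_with_distance"`.
#' @param base Base density (S/cm2).
#' @param slope Density slope per um (linear profile).
#' @param amp Sigmoid amplitude (S/cm2).
#' @param midpoint,steepness Sigmoid midpoint (um) and steepness (um).
#' @param clamp_lo,clamp_hi Density clamp bounds.
#' @return A `distribution_rule` object.
#' @export
distribution_rule <- function(channel, regions, profile = "uniform",
                              base = 0, slope = 0, amp = 0, midpoint = 150,
                              steepness = 50, clamp_lo = 0, clamp_hi = Inf) {
  profile <- match.arg(profile, c("uniform", "linear_with_distance",
                                  "sigmoidal_with_distance"))
  stopifnot(all(regions %in% .REGIONS))
  structure(list(channel = channel, regions = regions, profile = profile,
                 base = base, slope = slope, amp = amp, midpoint = midpoint,
                 steepness = steepness, clamp_lo = clamp_lo,
                 clamp_hi = clamp_hi),
            class = "distribution_rule")
}

.rule_density <- function(rule, dist) {
  d <- switch(rule$profile,
    uniform = rep_len(rule$base, length(dist)),
    linear_with_distance = rule$base + rule$slope * dist,
    sigmoidal_with_distance =
      rule$base + rule$amp / (1 + exp(-(dist - rule$midpoint) / rule$steepness)))
  pmin(pmax(d, rule$clamp_lo), rule$clamp_hi)
}

#' Per-compartment conductance densities
#'
#' Combines per-region peak conductances (uniform within a region) with
#' distance-dependent rules that override the uniform value for graded
#' channels.
#'
#' @param comps Compartment table from [discretize()].
#' @param rules List of [distribution_rule()] objects.
#' @param region_gbars Named list: `region_gbars[[channel]][[region]]` =
#'   density (S/cm2). Regions not listed get zero density.
#' @return Matrix (compartments x channels) of densities, S/cm2.
#' @export
apply_distributions <- function(comps, rules = list(), region_gbars = list()) {
  channels <- union(names(region_gbars),
                    vapply(rules, function(r) r$channel, character(1)))
  dens <- matrix(0, nrow(comps), length(channels),
                 dimnames = list(NULL, channels))
  for (ch in names(region_gbars)) {
    per_region <- region_gbars[[ch]]
    bad <- setdiff(names(per_region), .REGIONS)
    if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
    for (rg in names(per_region))
      dens[comps$region == rg, ch] <- per_region[[rg]]
  }
  for (rule in rules) {
    sel <- comps$region %in% rule$regions
    dens[sel, rule$channel] <- .rule_density(rule, comps$path_dist_um[sel])
  }
  if (any(dens < 0)) stop("negative density produced")
  dens
}

## ---- synapse placement ----------------------------------------------------

#' Synapse placement rule
#'
#' @param max_diameter Maximum dendrite diameter (um); synapses target the
#'   thinner apical dendrites (defaults: 1.0 mouse, 1.2 rat).
#' @param max_path_distance Maximum path distance from soma (um) (defaults:
#'   330 mouse, 360 rat).
#' @param eligible_regions Regions eligible for placement.
#' @return A `synapse_placement_rule`.
#' @export
synapse_placement_rule <- function(max_diameter, max_path_distance,
                                   eligible_regions = c("oblique",
                                                        "apical_trunk")) {
  stopifnot(max_diameter > 0, max_path_distance > 0)
  structure(list(max_diameter = max_diameter,
                 max_path_distance = max_path_distance,
                 eligible_regions = eligible_regions),
            class = "synapse_placement_rule")
}

#' Species synapse placement presets
#' @param species `"mouse"` or `"rat"`.
#' @return A [synapse_placement_rule()].
#' @export
synapse_rule_preset <- function(species = c("mouse", "rat")) {
  species <- match.arg(species)
  if (species == "mouse") synapse_placement_rule(1.0, 330)
  else synapse_placement_rule(1.2, 360)
}

#' Draw eligible synapse sites
#'
#' Samples `n` sites (with replacement) uniformly over eligible compartments,
#' weighted by compartment length.
#'
#' @param comps Compartment table from [discretize()].
#' @param rule A [synapse_placement_rule()].
#' @param n Number of synapses.
#' @param seed Integer seed (local RNG; global state untouched).
#' @return Data frame (comp, section, pos, path_dist_um, diam_um).
#' @export
eligible_synapse_sites <- function(comps, rule, n, seed = 1) {
  ok <- comps$region %in% rule$eligible_regions &
        comps$diam_um < rule$max_diameter &
        comps$path_dist_um <= rule$max_path_distance
  if (!any(ok)) stop("no eligible synapse sites")
  cand <- comps[ok, , drop = FALSE]
  idx <- with_local_seed(seed, sample.int(nrow(cand), n, replace = TRUE,
                                          prob = cand$length_um))
  out <- cand[idx, c("comp", "section", "pos", "path_dist_um", "diam_um")]
  rownames(out) <- NULL
  out
}

#' Evaluate randomness with a local, restorable RNG state
#'
#' All stochastic operations in the package draw through this helper so that
#' seeds are explicit and the caller's RNG state is never disturbed.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
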