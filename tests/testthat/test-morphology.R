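test_that("a toy SWC parses into soma plus one apical section", {
  m <- read_swc(toy_swc())
  expect_s3_class(m, "morphology")
  expect_equal(nrow(m$sections), 2)
  expect_true(is.na(m$sections$parent[1]))
  comps <- discretize(m)
  child <- comps[comps$region != "soma", ]
  expect_equal(nrow(child), 1)
  expect_equal(child$length_um, 10)
  # path distance from the soma center to the section midpoint
  expect_equal(child$path_dist_um, 5)
})

test_that("malformed SWC files are rejected", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 4 10 0 0 1 3",
               "3 4 20 0 0 1 1"), f) # forward reference
  expect_error(read_swc(f), "later line")
  writeLines(c("1 1 0 0 0 5 -1", "2 4 10 0 0 1 -1"), f)
  expect_error(read_swc(f), "root")
  writeLines(c("1 1 0 0 0 0 -1"), f)
  expect_error(read_swc(f), "radius")
})

test_that("the shipped synthetic CA1 SWC has the documented regions", {
  f <- system.file("extdata", "swc", "ca1_synthetic.swc",
                   package = "ca1pyr")
  m <- read_swc(f)
  counts <- table(m$sections$region)
  # counts documented in the fixture header; verified by brute-force count
  raw <- readLines(f)
  doc <- raw[grepl("^# region_counts", raw)]
  expected <- eval(parse(text = sub("^# region_counts ", "", doc)))
  expect_equal(as.list(counts)[names(expected)], expected)
  # trunk/oblique labeling puts the obliques off the maximal-diameter path
  expect_gt(mean(m$sections$diam_dist_um[m$sections$region ==
                                           "apical_trunk"]),
            mean(m$sections$diam_dist_um[m$sections$region == "oblique"]))
})

test_that("write_swc / read_swc round-trips geometry", {
  m <- build_reduced_morphology("mouse")
  f <- tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_equal(sum(m2$sections$length_um[m2$sections$region != "soma"]),
               sum(m$sections$length_um[m$sections$region != "soma"]),
               tolerance = 1e-6)
  expect_setequal(unique(m2$sections$region), unique(m$sections$region))
})

test_that("reduced morphologies encode the species geometry trends", {
  mm <- build_reduced_morphology("mouse")
  mr <- build_reduced_morphology("rat")
  cm <- discretize(mm)
  cr <- discretize(mr)
  # rat trunk thicker than mouse at matched distances
  for (d in c(50, 100, 200, 300)) {
    dm <- cm[cm$region == "apical_trunk", ]
    dr <- cr[cr$region == "apical_trunk", ]
    expect_gt(dr$diam_um[which.min(abs(dr$path_dist_um - d))],
              dm$diam_um[which.min(abs(dm$path_dist_um - d))])
  }
  # rat has more total dendrite (lower input resistance)
  dend <- function(m) sum(m$sections$length_um[
    m$sections$region %in% c("basal", "apical_trunk", "oblique")])
  expect_gt(dend(mr), dend(mm))
  # total dendritic length equals the sum of its section lengths
  g <- reduced_morphology_preset("mouse")
  expect_equal(dend(mm), g$trunk_L + length(g$oblique_offsets) *
                 g$oblique_L + g$n_basal * g$basal_L)
})

test_that("linear taper interpolates and rejects impossible geometry", {
  g <- reduced_morphology_preset("mouse")
  g$trunk_L <- 400
  g$trunk_diam0 <- 2
  g$trunk_diam1 <- 1
  g$oblique_offsets <- 200
  m <- build_reduced_morphology(g)
  tr <- m$sections[m$sections$region == "apical_trunk", ]
  expect_equal(tr$diam_dist_um[1], 1.5) # at the 200 um cut
  g$trunk_diam1 <- -1
  expect_error(build_reduced_morphology(g), "non-positive")
})

test_that("path distance is additive along root-to-tip paths", {
  comps <- discretize(build_reduced_morphology("mouse"))
  g <- reduced_morphology_preset("mouse")
  for (i in seq_along(g$oblique_offsets)) {
    ob <- comps[comps$section == sprintf("oblique_%d", i), ]
    expect_equal(ob$path_dist_um, g$oblique_offsets[i] + ob$pos * g$oblique_L)
  }
  # every compartment's path distance exceeds its parent's (off the soma)
  nonsoma <- comps[!is.na(comps$parent_comp) & comps$region != "soma", ]
  parents <- comps$path_dist_um[nonsoma$parent_comp]
  expect_true(all(nonsoma$path_dist_um >= parents - 1e-9))
})

test_that("density maps follow the distribution rules", {
  comps <- discretize(build_reduced_morphology("mouse"))
  rules <- list(distribution_rule("Ih", c("apical_trunk", "oblique"),
                                  "linear_with_distance", base = 1e-5,
                                  slope = 1e-7))
  gbars <- list(KDR = list(apical_trunk = 0.01))
  dens <- apply_distributions(comps, rules, gbars)
  ap <- comps$region == "apical_trunk"
  expect_true(all(dens[ap, "KDR"] == 0.01))
  expect_true(all(dens[!ap, "KDR"] == 0))
  # linear profile: base + slope * distance (4e-5 at 300 um)
  i300 <- which(ap)[which.min(abs(comps$path_dist_um[ap] - 300))]
  expect_equal(unname(dens[i300, "Ih"]),
               1e-5 + 1e-7 * comps$path_dist_um[i300])
  expect_true(all(dens >= 0))
  # graded densities are monotone in path distance within the region
  ord <- order(comps$path_dist_um[ap])
  expect_true(all(diff(dens[which(ap)[ord], "Ih"]) >= -1e-15))
  # negative slopes clamp at zero instead of going negative
  neg <- list(distribution_rule("Ih", "oblique", "linear_with_distance",
                                base = 1e-5, slope = -1))
  d2 <- apply_distributions(comps, neg, list())
  expect_true(all(d2[, "Ih"] >= 0))
  expect_error(apply_distributions(comps, list(),
                                   list(KDR = list(nucleus = 1))),
               "unknown region")
})

test_that("synapse placement respects the species eligibility rules", {
  comps <- placement_comps()
  mouse <- eligible_synapse_sites(comps, synapse_rule_preset("mouse"),
                                  n = 50, seed = 7)
  expect_setequal(unique(mouse$comp), 1L) # only diam 0.8 within 330 um
  rat <- eligible_synapse_sites(comps, synapse_rule_preset("rat"),
                                n = 200, seed = 7)
  expect_setequal(unique(rat$comp), 1:3)
  # reproducible under seed
  again <- eligible_synapse_sites(comps, synapse_rule_preset("rat"),
                                  n = 200, seed = 7)
  expect_identical(rat, again)
  # 80 sites on the mouse preset, all satisfying the rule
  cell <- cell_preset("mouse")
  rule <- synapse_rule_preset("mouse")
  sites <- eligible_synapse_sites(cell$comps, rule, 80, seed = 1)
  expect_equal(nrow(sites), 80)
  expect_true(all(sites$diam_um < rule$max_diameter))
  expect_true(all(sites$path_dist_um <= rule$max_path_distance))
  # no eligible section is an error
  strict <- synapse_placement_rule(0.1, 10)
  expect_error(eligible_synapse_sites(comps, strict, 5), "no eligible")
})
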