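test_that("generated connectomes have the closed-form population structure", {
  cfg <- generator_config(n_lineages = 2, temporal_groups_per_hemilineage = 2,
                          neurons_per_hlt = 3, seed = 7)
  cn <- suppressMessages(generate_connectome(cfg))
  ann <- cn$annotations
  # 2 lineages x 2 hemilineages x 2 groups x 3 neurons x 2 sides
  expect_equal(sum(ann$cell_class == "interneuron"), 48L)
  expect_equal(sum(ann$cell_class == "sensory"), 2L * cfg$n_sensory)
  expect_equal(sum(ann$cell_class == "motor"), 2L * cfg$n_motor)
  expect_equal(length(cn$skeletons), nrow(ann))
  expect_true(all(vapply(cn$skeletons, function(s) nrow(s$nodes), 1L) >= 1L))
  # equal left/right homolog counts
  expect_equal(sum(ann$hemisegment == "left"), sum(ann$hemisegment == "right"))
  expect_true(all(table(ann$homolog_id) == 2L))
})

test_that("generation is exactly reproducible from the seed", {
  cfg <- generator_config(n_lineages = 2, temporal_groups_per_hemilineage = 2,
                          neurons_per_hlt = 2, seed = 31)
  c1 <- suppressMessages(generate_connectome(cfg))
  c2 <- suppressMessages(generate_connectome(cfg))
  expect_identical(c1$connectors, c2$connectors)
  expect_identical(c1$skeletons, c2$skeletons)
  expect_identical(c1$designated_pairs, c2$designated_pairs)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(c1, d1)
  write_fixture(c2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("fixtures round-trip through the core readers", {
  cn <- small_connectome()
  dir <- withr::local_tempdir()
  write_fixture(cn, dir)
  expect_error(write_fixture(cn, dir), "overwrite")
  expect_equal(length(list.files(file.path(dir, "skeletons"), "\\.swc$")),
               length(cn$skeletons))

  back <- read_connectome(dir)
  expect_equal(as.data.frame(back$annotations),
               as.data.frame(cn$annotations))
  expect_equal(nrow(back$connectors), nrow(cn$connectors))
  expect_equal(sort(names(back$skeletons)), sort(names(cn$skeletons)))
  expect_equal(back$config$seed, cn$config$seed)
  expect_equal(back$reference_lengths$hb, cn$reference_lengths$hb,
               tolerance = 1e-12)
  # connectors.csv rows = total (connector, partner) contacts
  tab <- utils::read.csv(file.path(dir, "connectors.csv"))
  expect_equal(nrow(tab), sum(table(cn$connectors$connector_id)))
  # clouds restored for every neuron that has them
  expect_equal(back$pre_clouds[["NB1_dorsal_T1_n1_L"]][, ],
               cn$pre_clouds[["NB1_dorsal_T1_n1_L"]][, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("mirrored hemisegments are bilaterally symmetric up to jitter", {
  cn <- small_connectome()
  ann <- cn$annotations
  np <- cn$config$neuropil
  lens <- vapply(cn$skeletons, cortex_neurite_length, numeric(1),
                 volume = np)
  left <- ann[ann$hemisegment == "left", ]
  right <- ann[ann$hemisegment == "right", ]
  l <- lens[left$neuron_id[order(left$homolog_id)]]
  r <- lens[right$neuron_id[order(right$homolog_id)]]
  expect_true(mean(abs(l - r)) <= 2 * cn$config$mirror_jitter_sd)
  # soma x positions mirror
  sx_l <- vapply(cn$skeletons[left$neuron_id], function(s) s$nodes$x[1],
                 numeric(1))
  sx_r <- vapply(cn$skeletons[right$neuron_id[match(left$homolog_id,
                                                    right$homolog_id)]],
                 function(s) s$nodes$x[1], numeric(1))
  expect_true(all(abs(sx_l + sx_r) < 6 * cn$config$mirror_jitter_sd))
})

test_that("cortex neurite lengths increase with temporal group", {
  cn <- default_connectome()
  ann <- cn$annotations
  inter <- ann[ann$cell_class == "interneuron", ]
  truth <- cn$cortex_length_truth[inter$neuron_id]
  means <- tapply(truth, inter$temporal_group, mean)
  expect_true(all(diff(means) > 0))
  expect_true(all(diff(means) > cn$config$radial_noise_sd))
})

test_that("dorsal and ventral synapse clouds occupy opposite neuropil halves", {
  cn <- small_connectome()
  ann <- cn$annotations
  for (hl in c("dorsal", "ventral")) {
    ids <- ann$neuron_id[ann$hemilineage == hl &
                           ann$cell_class == "interneuron"]
    clustered <- if (hl == "dorsal") cn$pre_clouds[ids] else
      cn$post_clouds[ids]
    frac_side <- mean(do.call(rbind, clustered)[, 2] > 0)
    if (hl == "dorsal") expect_gt(frac_side, 0.9)
    else expect_lt(frac_side, 0.1)
  }
})

test_that("the cohort bonus monotonically raises designated-pair connectivity", {
  designated_rate <- function(eps, seed) {
    cfg <- generator_config(n_lineages = 2,
                            temporal_groups_per_hemilineage = 2,
                            neurons_per_hlt = 2, hlt_bonus = eps,
                            seed = seed)
    cn <- suppressMessages(generate_connectome(cfg))
    ann <- cn$annotations
    b <- binarize(suppressMessages(
      build_connectivity(cn$connectors, ann$neuron_id)), 1)
    coh <- hlt_cohort(ann)
    cl <- split(names(coh)[!is.na(coh)], coh[!is.na(coh)])
    des <- cn$designated_pairs
    hits <- 0
    tot <- 0
    for (r in seq_len(nrow(des))) {
      src <- cl[[des$from[r]]]
      tgt <- cl[[des$to[r]]]
      hits <- hits + sum(b[src, tgt, drop = FALSE] > 0)
      tot <- tot + length(src) * length(tgt)
    }
    hits / tot
  }
  seeds <- 1:20
  rates <- vapply(c(0, 1, 4), function(eps)
    mean(vapply(seeds, function(s) designated_rate(eps, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("a neuropil too small for the cloud separation is rejected", {
  expect_error(generator_config(
    neuropil = neuropil_ellipsoid(radii = c(40000, 8000, 60000)),
    cluster_sd = 6000), "too small")
})
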