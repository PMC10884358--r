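test_that("findings records normalize the effect vocabulary", {
  f <- validate_finding("4", "Hypnagogic state vs. wake", "More Duration")
  expect_equal(f$direction, "More")
  expect_equal(f$parameter, "Duration")

  f2 <- validate_finding("C", "", "No findings")
  expect_equal(f2$direction, "NoFinding")
  expect_equal(f2$parameter, "")

  f3 <- validate_finding("G", "Right inferior parietal lobe",
                         "More current density")
  expect_equal(f3$parameter, "CurrentDensity")

  f4 <- validate_finding("E", "Meditation vs. rest", "Less alpha power")
  expect_equal(f4$parameter, "Other")
  expect_equal(f4$parameter_detail, "alpha power")

  expect_error(validate_finding("X", "", "More Duration"), "contrast")
  expect_error(validate_finding("X", "a vs. b", "Higher Duration"),
               "direction")
  expect_error(validate_finding("X", "a vs. b", "No findings"),
               "empty contrast")
})

test_that("selection queries return exactly the selected maps' findings", {
  m <- montage_1020()
  fnd <- data.frame(
    map_label = c("D", "D", "C"),
    contrast = c("Females compared to males",
                 "Young adults (20-30y) against adolescents (14-19y)", ""),
    effect = c("Less Occurrence", "More Occurrence", "No findings"))
  s1 <- toy_study("Tomescu 2018", seed = 1, n_maps = 4, findings = fnd)
  s2 <- toy_study("Other 2020", seed = 2, n_maps = 2)
  at <- ms_atlas(list(s1, s2))

  tab <- query_findings(at, data.frame(study_id = "Tomescu 2018",
                                       map_label = "D"))
  expect_equal(nrow(tab), 2L)
  expect_true(any(tab$contrast == "Females compared to males" &
                    tab$direction == "Less" & tab$parameter == "Occurrence"))

  ## a selected map without findings yields one NoFinding row
  tab2 <- query_findings(at, data.frame(study_id = "Other 2020",
                                        map_label = "A"))
  expect_equal(nrow(tab2), 1L)
  expect_equal(tab2$direction, "NoFinding")

  ## union of disjoint selections equals re-sorted concatenation
  selA <- data.frame(study_id = "Tomescu 2018", map_label = c("C", "D"))
  selB <- data.frame(study_id = "Other 2020", map_label = "A")
  both <- query_findings(at, rbind(selA, selB))
  parts <- rbind(query_findings(at, selA), query_findings(at, selB))
  parts <- parts[order(parts$study_id, parts$map_label, parts$parameter,
                       parts$direction, parts$contrast, method = "radix"), ]
  expect_equal(as.data.frame(both), as.data.frame(parts),
               ignore_attr = TRUE)

  expect_error(query_findings(at, data.frame(study_id = "Nope",
                                             map_label = "A")),
               "unknown map")
  ## queries are pure: repeated calls identical
  expect_identical(query_findings(at, selA), query_findings(at, selA))
})

test_that("meta-class queries partition the atlas's maps", {
  at <- sim_atlas(n_studies = 5, seed = 7)
  m <- montage_1020()
  sol <- as_metasolution(prototype_maps(attr(at, "prototypes"), m), m)
  bf <- backfit_maps(sol, at)
  seen <- list()
  for (k in seq_len(sol$K)) {
    tab <- query_metaclass_findings(at, sol, k)
    keys <- unique(paste(tab$study_id, tab$map_label))
    want <- paste(bf$study_id, bf$map_label)[bf$class == k]
    expect_setequal(keys, want)
    seen[[k]] <- keys
  }
  all_keys <- unlist(seen)
  expect_equal(sort(all_keys),
               sort(paste(bf$study_id, bf$map_label)))
  expect_false(anyDuplicated(all_keys) > 0)
})

test_that("an unpopulated meta-class yields an empty provenance-noted table", {
  m <- montage_1020()
  pr <- sim_prototypes(3, m, seed = 9)
  sol <- as_metasolution(pr$maps, m)
  ## single study whose only map is prototype 1
  s <- ms_study("Solo", m, cbind(A = pr$maps[, 1]), 8)
  tab <- query_metaclass_findings(ms_atlas(list(s)), sol, 2)
  expect_equal(nrow(tab), 0L)
  expect_match(attr(tab, "provenance"), "no assigned maps")
  expect_error(query_metaclass_findings(ms_atlas(list(s)), sol, 9),
               "1\\.\\.3")
})

test_that("findings tables export to CSV and re-import unchanged", {
  m <- montage_1020()
  fnd <- data.frame(
    map_label = c("F", "F", "4"),
    contrast = c("Critical helicopter landing maneuver vs. resting state",
                 "Critical helicopter landing maneuver vs. resting state",
                 "Hypnagogic state vs. wake"),
    effect = c("Less Contribution", "Less Duration", "More Occurrence"))
  s <- ms_study("Demo 2021", m,
                {
                  mm <- withr::with_seed(1, matrix(rnorm(19 * 2), ncol = 2))
                  colnames(mm) <- c("F", "4"); mm
                }, 12, findings = fnd)
  at <- ms_atlas(list(s))
  tab <- query_findings(at, data.frame(study_id = "Demo 2021",
                                       map_label = c("F", "4")))
  path <- withr::local_tempfile(fileext = ".csv")
  export_findings(tab, path)
  back <- read_findings(path)
  cols <- c("study_id", "map_label", "contrast", "direction", "parameter",
            "parameter_detail")
  expect_equal(as.data.frame(back)[cols], as.data.frame(tab)[cols],
               ignore_attr = TRUE)

  ## empty table -> header-only file that reads back empty
  pr <- sim_prototypes(3, m, seed = 9)
  solo <- ms_study("Solo", m, cbind(A = pr$maps[, 1]), 8)
  empty <- query_metaclass_findings(ms_atlas(list(solo)),
                                    as_metasolution(pr$maps, m), 2)
  export_findings(empty, path)
  expect_equal(nrow(read_findings(path)), 0L)
  expect_equal(length(readLines(path)), 1L)
})
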