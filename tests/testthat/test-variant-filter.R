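fixture_path <- function(name) system.file("extdata", name, package = "ithbench")

test_that("caller FILTER rule matches the per-caller allowed sets", {
  expect_true(caller_filter_pass("Mutect2", "panel_of_normals"))
  expect_true(caller_filter_pass("Mutect2", "PASS"))
  expect_false(caller_filter_pass("VarScan2", "germline"))
  expect_true(caller_filter_pass("MuSe", "Tier3"))
  expect_false(caller_filter_pass("MuSe", "Tier6"))
  expect_false(caller_filter_pass("SomaticSniper", "Tier1"))
  expect_error(caller_filter_pass("Strelka", "PASS"), "unknown caller")
})

test_that("population rule removes common variants unless in COSMIC", {
  expect_false(population_filter_pass(0.02, NA, FALSE))
  expect_true(population_filter_pass(0.02, NA, TRUE))
  expect_true(population_filter_pass(NA, NA, FALSE))
  expect_true(population_filter_pass(0.01, 0.01, FALSE))  # strictly greater
  expect_false(population_filter_pass(NA, 0.011, FALSE))
})

test_that("coverage rule applies normal and tumor clauses with strict VAF ties", {
  expect_true(coverage_filter_pass(10, 0, 8, 3))
  expect_false(coverage_filter_pass(5, 0, 100, 50))
  expect_false(coverage_filter_pass(200, 2, 20, 10))   # normal VAF == 0.01
  expect_true(coverage_filter_pass(300, 2, 20, 10))    # normal VAF < 0.01
  expect_false(coverage_filter_pass(10, 0, 100, 2))    # tumor VAF 0.02, alt < 3
  expect_true(coverage_filter_pass(10, 0, 9, 2))       # tumor VAF 2/9 > 0.2
  expect_false(coverage_filter_pass(0, 0, 60, 20))     # zero depth fails
})

make_record <- function(mutation_id, caller = "Mutect2",
                        filter_status = "PASS", is_indel = FALSE,
                        af_1000g = NA, af_exac = NA, in_cosmic = FALSE,
                        normal = c(30, 0), tumor = c(60, 20)) {
  data.frame(mutation_id = mutation_id, is_indel = is_indel, caller = caller,
             filter_status = filter_status, af_1000g = af_1000g,
             af_exac = af_exac, in_cosmic = in_cosmic,
             normal_depth = normal[1], normal_alt = normal[2],
             tumor_depth = tumor[1], tumor_alt = tumor[2],
             stringsAsFactors = FALSE)
}

test_that("public set is the indel-free union of caller outputs", {
  caller_a <- rbind(make_record("A", caller = "MuSe", filter_status = "Tier1"),
                    make_record("B", caller = "MuSe", filter_status = "Tier1"))
  caller_b <- rbind(make_record("B"), make_record("C"),
                    make_record("D", is_indel = TRUE))
  pub <- build_mutation_sets(list(caller_a, caller_b), mode = "public")
  expect_setequal(pub$mutation_id, c("A", "B", "C"))
  prot <- build_mutation_sets(list(caller_a, caller_b), mode = "protected")
  expect_false("D" %in% prot$mutation_id)
})

test_that("duplicate ids resolve to the deepest tumor record", {
  recs <- rbind(make_record("A", tumor = c(50, 10)),
                make_record("A", caller = "VarScan2", tumor = c(90, 30)))
  out <- build_mutation_sets(recs, mode = "public")
  expect_identical(nrow(out), 1L)
  expect_identical(out$tumor_depth, 90)
})

test_that("protected mode equals independent composition of the three predicates", {
  set.seed(31)
  n <- 300
  recs <- data.frame(
    mutation_id = sprintf("m%03d", sample(150, n, replace = TRUE)),
    is_indel = runif(n) < 0.1,
    caller = sample(c("MuSe", "Mutect2", "VarScan2", "SomaticSniper"), n, TRUE),
    filter_status = sample(c("PASS", "panel_of_normals", "Tier1", "Tier6",
                             "germline"), n, TRUE),
    af_1000g = ifelse(runif(n) < 0.5, NA, runif(n, 0, 0.05)),
    af_exac = ifelse(runif(n) < 0.5, NA, runif(n, 0, 0.05)),
    in_cosmic = runif(n) < 0.2,
    normal_depth = rpois(n, 30), normal_alt = rpois(n, 0.5),
    tumor_depth = rpois(n, 60), tumor_alt = rpois(n, 10),
    stringsAsFactors = FALSE)
  recs$normal_alt <- pmin(recs$normal_alt, recs$normal_depth)
  recs$tumor_alt <- pmin(recs$tumor_alt, recs$tumor_depth)
  # oracle: row-by-row predicate composition, then union by id
  keep <- logical(n)
  for (r in seq_len(n)) {
    row <- recs[r, ]
    ok <- !row$is_indel
    ok <- ok && tryCatch(caller_filter_pass(row$caller, row$filter_status),
                         error = function(e) FALSE)
    af1 <- if (is.na(row$af_1000g)) 0 else row$af_1000g
    af2 <- if (is.na(row$af_exac)) 0 else row$af_exac
    ok <- ok && !((af1 > 0.01 || af2 > 0.01) && !row$in_cosmic)
    nv <- if (row$normal_depth > 0) row$normal_alt / row$normal_depth else 1
    tv <- if (row$tumor_depth > 0) row$tumor_alt / row$tumor_depth else 0
    ok <- ok && row$normal_depth >= 6 && (row$normal_alt <= 1 || nv < 0.01)
    ok <- ok && row$tumor_depth >= 8 && (row$tumor_alt >= 3 || tv > 0.2)
    keep[r] <- ok
  }
  expected_ids <- sort(unique(recs$mutation_id[keep]))
  got <- build_mutation_sets(recs, mode = "protected")
  expect_identical(sort(got$mutation_id), expected_ids)
})

test_that("filtering is idempotent and a subset of its input", {
  set.seed(32)
  recs <- rbind(make_record("A"), make_record("B", filter_status = "artifact"),
                make_record("C", af_1000g = 0.2),
                make_record("E", normal = c(4, 0)))
  once <- build_mutation_sets(recs, mode = "protected")
  twice <- build_mutation_sets(once, mode = "protected")
  expect_true(all(once$mutation_id %in% recs$mutation_id))
  expect_identical(sort(once$mutation_id), sort(twice$mutation_id))
  expect_warning(build_mutation_sets(recs[0, ], mode = "protected"), "empty")
})

test_that("the fixture VCF reproduces the tabulated per-rule pattern", {
  recs <- read_caller_vcf(fixture_path("fixture_caller_records.vcf"))
  expected <- read.delim(fixture_path("fixture_caller_records_expected.tsv"))
  expect_identical(nrow(recs), 20L)
  recs <- recs[match(expected$mutation_id, recs$mutation_id), ]
  expect_identical(recs$is_indel, expected$is_indel)
  expect_identical(unname(caller_filter_pass(recs$caller, recs$filter_status)),
                   expected$caller_pass)
  expect_identical(population_filter_pass(recs$af_1000g, recs$af_exac,
                                          recs$in_cosmic),
                   expected$population_pass)
  expect_identical(coverage_filter_pass(recs$normal_depth, recs$normal_alt,
                                        recs$tumor_depth, recs$tumor_alt),
                   expected$coverage_pass)
  prot <- build_mutation_sets(recs, mode = "protected")
  pub <- build_mutation_sets(recs, mode = "public")
  expect_setequal(prot$mutation_id,
                  expected$mutation_id[expected$in_protected])
  expect_setequal(pub$mutation_id, expected$mutation_id[expected$in_public])
})
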