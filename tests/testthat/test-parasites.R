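# A small marsh-like web: bird eats fish and snail, fish eats snail and
# copepod, snail grazes nothing.
marshWeb <- function() {
  labs <- c("bird", "fish", "snail", "copepod")
  a <- matrix(0L, 4, 4, dimnames = list(labs, labs))
  a["bird", c("fish", "snail")] <- 1L
  a["fish", c("snail", "copepod")] <- 1L
  FoodWeb(a)
}

test_that("the viability rule keeps supported cycles and drops broken ones", {
  fw <- marshWeb()
  recs <- makeRecords(
    makeRecord("fluke", list("snail", "bird")),          # bird eats snail
    makeRecord("lost", list("mussel", "bird")),          # no mussel here
    makeRecord("worm", list("copepod", "fish", "bird"))) # full chain
  expect_warning(v <- filterViableParasites(fw, recs), "mussel")
  tab <- recordsTable(v)
  expect_setequal(unique(tab$parasite), c("fluke", "worm"))
})

test_that("trophic-transition support is required only under the strict rule", {
  fw <- marshWeb()
  # both hosts present, but birds do not eat copepods
  recs <- makeRecords(makeRecord("gap", list("copepod", "bird")))
  strict <- filterViableParasites(fw, recs)
  expect_equal(nParasites(strict), 0L)
  loose <- filterViableParasites(fw, recs, requireTrophicSupport = FALSE)
  expect_equal(nParasites(loose), 1L)
  # non-trophic acquisition is exempt from the link check
  direct <- makeRecords(makeRecord("skin", list("copepod", "bird"),
                                   transmission = c("direct", "direct")))
  expect_equal(nParasites(filterViableParasites(fw, direct)), 1L)
})

test_that("free-living environment stages are always present", {
  fw <- marshWeb()
  recs <- makeRecords(makeRecord("free", list("environment", "snail"),
                                 transmission = c("direct", "direct")))
  expect_equal(nParasites(filterViableParasites(fw, recs)), 1L)
})

test_that("removing a species never rescues a parasite (monotone filter)", {
  set.seed(31)
  for (rep in 1:5) {
    fw <- randomWeb(12, p = 0.3, seed = rep + 40)
    labs <- speciesLabels(fw)
    recs <- makeRecords(
      makeRecord("p1", list(sample(labs, 2), sample(labs, 2))),
      makeRecord("p2", list(sample(labs, 3))),
      makeRecord("p3", list(sample(labs, 2), sample(labs, 2),
                            sample(labs, 2))))
    keep <- setdiff(seq_along(labs), sample(seq_along(labs), 1))
    sub <- FoodWeb(adjacency(fw)[keep, keep])
    vFull <- unique(recordsTable(
      suppressWarnings(filterViableParasites(fw, recs)))$parasite)
    vSub <- unique(recordsTable(
      suppressWarnings(filterViableParasites(sub, recs)))$parasite)
    expect_true(all(vSub %in% vFull))
  }
})

test_that("parasite-implied links are added once and never removed", {
  fw <- marshWeb()
  a <- adjacency(fw)
  a["bird", "snail"] <- 0L  # remove the known link
  fw0 <- FoodWeb(a)
  recs <- makeRecords(makeRecord("fluke", list("snail", "bird")))
  # strict viability would drop the parasite, so apply unfiltered
  out <- inferTrophicLinks(fw0, recs, filtered = TRUE)
  expect_identical(adjacency(out$web)["bird", "snail"], 1L)
  expect_equal(nrow(out$provenance), 1L)
  expect_equal(out$provenance$parasite, "fluke")
  # idempotence: applying twice equals applying once
  again <- inferTrophicLinks(out$web, recs, filtered = TRUE)
  expect_identical(adjacency(again$web), adjacency(out$web))
  expect_equal(nrow(again$provenance), 0L)
  # links are never removed
  expect_true(all(adjacency(out$web) >= adjacency(fw0)))
  expect_gte(sum(adjacency(out$web)), sum(adjacency(fw0)))
})

test_that("host richness counts each parasite once per host", {
  fw <- marshWeb()
  recs <- makeRecords(
    makeRecord("fluke", list("snail", "bird")),
    makeRecord("worm", list("copepod", "fish", "bird")),
    makeRecord("round", list("snail", "snail"))) # same host at two stages
  v <- filterViableParasites(fw, recs, requireTrophicSupport = FALSE)
  hr <- hostRichness(fw, v)
  expect_equal(hr$richness[hr$label == "bird"], 2)
  expect_equal(hr$richness[hr$label == "snail"], 2)
  expect_equal(hr$richness[hr$label == "copepod"], 1)
  # double-counting identity
  tabs <- trophicnets:::.recordList(v)
  perParasite <- vapply(tabs, function(r)
    length(intersect(unique(unlist(r$stages)), speciesLabels(fw))),
    numeric(1))
  expect_equal(sum(hr$richness), sum(perParasite))
})

test_that("a focal host accumulates the richness of its whole record set", {
  labs <- c("killifish", sprintf("x%02d", 1:9))
  a <- matrix(0L, 10, 10, dimnames = list(labs, labs))
  a[1, -1] <- 1L
  fw <- FoodWeb(a)
  recs <- do.call(makeRecords, lapply(1:10, function(i)
    makeRecord(sprintf("hel%02d", i), list("killifish"))))
  v <- filterViableParasites(fw, recs)
  hr <- hostRichness(fw, v)
  expect_equal(hr$richness[hr$label == "killifish"], 10)
  expect_equal(hr$richness[hr$label == "x01"], 0)
})

test_that("every host in all records reaches full richness", {
  labs <- sprintf("h%02d", 1:6)
  a <- matrix(0L, 6, 6, dimnames = list(labs, labs))
  a[1, 2] <- 1L
  fw <- FoodWeb(a)
  recs <- do.call(makeRecords, lapply(1:25, function(i)
    makeRecord(sprintf("p%02d", i), list(c("h01", sample(labs, 1))))))
  v <- filterViableParasites(fw, recs)
  hr <- hostRichness(fw, v)
  expect_equal(hr$richness[hr$label == "h01"], 25)
})

test_that("parasite tables round-trip through CSV", {
  recs <- makeRecords(
    makeRecord("fluke", list(c("snail", "mussel"), "bird")),
    makeRecord("worm", list("copepod", "fish", "bird")))
  f <- withr::local_tempfile(fileext = ".csv")
  writeParasiteTable(recs, f)
  back <- readParasiteTable(f)
  expect_identical(recordsTable(back), recordsTable(recs))
})

test_that("records validity enforces stage numbering and modes", {
  bad <- data.frame(parasite = "p", stage_index = c(1, 3),
                    stage_role = "x", transmission = "trophic",
                    hosts = "a", source = "literature")
  expect_error(parasiteRecords(bad), "1..k")
  bad2 <- data.frame(parasite = "p", stage_index = 1, stage_role = "x",
                     transmission = "psychic", hosts = "a",
                     source = "literature")
  expect_error(parasiteRecords(bad2), "transmission")
})
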