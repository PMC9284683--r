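test_that("a title-only document yields a card with no sections", {
  card <- read_card("card_id: minimal\ntitle: A minimal card\n")
  expect_s3_class(card, "model_card")
  expect_equal(card$card_id, "minimal")
  expect_length(card$sections, 0)
  expect_identical(card, read_card(write_card(card)))
})

test_that("the stent-implantation sample card loads with its documented content", {
  card <- read_card(fixture_card_path("pci-adverse-endpoints.yaml"))
  expect_equal(card$title,
               "Adverse endpoints prediction for patients undergoing PCI")
  details <- Filter(function(s) s$kind == "ModelDetails", card$sections)
  expect_length(details, 1)
  expect_match(details[[1]]$body, "recurrent neural network")
  expect_match(details[[1]]$body, "coronary artery stent implantation")
  # sample structure covers at least trade-offs and users
  kinds <- unlist(lapply(card$sections, function(s)
    c(s$kind, vapply(s$children, `[[`, "", "kind"))))
  expect_true(all(c("TradeOff", "User") %in% kinds))
})

test_that("the HIV social-network sample card loads and validates", {
  card <- read_card(fixture_card_path("hiv-social-network.yaml"))
  expect_equal(card$title,
               "Incorporating social network information to predict HIV status")
  details <- Filter(function(s) s$kind == "ModelDetails", card$sections)
  expect_match(details[[1]]$body, "graph convolutional network")
})

test_that("dates must be ISO 8601 (validated against as.Date)", {
  # oracle: what base R's strict date parser accepts
  oracle_ok <- function(x) !is.na(as.Date(x, format = "%Y-%m-%d")) &&
    grepl("^\\d{4}-\\d{2}-\\d{2}", x)
  good <- "2022-07-14"; bad <- c("14-07-2022", "2022-13-40", "July 14 2022")
  expect_true(oracle_ok(good))
  expect_no_error(model_card("c", "t", list(
    card_section("Considerations", annotations = list(date = good)))))
  for (d in bad) {
    expect_false(oracle_ok(d))
    expect_error(model_card("c", "t", list(
      card_section("Considerations", annotations = list(date = d)))),
      "ISO 8601")
  }
})

test_that("unknown kinds and invalid nesting are rejected with vocabulary hints", {
  expect_error(read_card(
    "card_id: x\ntitle: t\nsections:\n  - kind: Frobnication\n"),
    "allowed kinds")
  # TradeOff is a part of Considerations, not of ModelParameters
  expect_error(model_card("x", "t", list(
    card_section("ModelParameters",
                 children = list(card_section("TradeOff"))))),
    "not a schema-valid part")
  expect_error(read_card("just text, no mapping"), "malformed")
  expect_error(model_card("", "t"), "non-empty")
  expect_error(model_card("c", "t", list(
    card_section("Considerations", annotations = list(color = "red")))),
    "unknown annotation")
})

test_that("write -> read round-trips cards, preserving nesting order", {
  for (f in c("pci-adverse-endpoints.yaml", "hiv-social-network.yaml")) {
    card <- read_card(fixture_card_path(f))
    expect_identical(card, read_card(write_card(card)))
  }
  nested <- model_card("nested", "Nesting order", list(
    card_section("Considerations", children = list(
      card_section("TradeOff", heading = "first"),
      card_section("EthicalConsideration", heading = "second"),
      card_section("TradeOff", heading = "third")))))
  back <- read_card(write_card(nested))
  expect_identical(vapply(back$sections[[1]]$children, `[[`, "", "heading"),
                   c("first", "second", "third"))
  expect_identical(nested, back)
})

test_that("the synthetic card generator is seeded, schema-valid and round-trips", {
  expect_length(generate_card(1, 0, 1)$sections, 0)
  expect_identical(generate_card(42, 5, 2), generate_card(42, 5, 2))
  expect_false(identical(generate_card(42, 5, 2), generate_card(43, 5, 2)))
  for (seed in 1:5) {
    card <- generate_card(seed, 50, 3)
    expect_equal(count_sections(card), 50)
    expect_no_error(validate_card(card))
    expect_identical(card, read_card(write_card(card)))
  }
  # every generated section carries description and date annotations
  card <- generate_card(7, 20, 3)
  check_ann <- function(s) {
    expect_true(all(c("description", "date") %in% names(s$annotations)))
    lapply(s$children, check_ann)
  }
  invisible(lapply(card$sections, check_ann))
  # generator does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_card(1, 10, 2)); after <- runif(1)
  expect_identical(before, after)
})

test_that("section counting agrees with an independent tree walk", {
  for (seed in 1:5) {
    card <- generate_card(seed, sample(0:30, 1), 3)
    expect_equal(count_sections(card), oracle_section_count(card))
  }
})
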