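test_that("canonical unit table matches the cross-domain analogy scheme", {
  expect_equal(canonicalUnit("electrical", "flow"), "A")
  expect_equal(canonicalUnit("electrical", "force"), "V")
  expect_equal(canonicalUnit("fluid", "force"), "Pa")
  expect_equal(canonicalUnit("fluid", "amount"), "m^3")
  expect_equal(canonicalUnit("chemical", "force"), "J/mol")
  expect_equal(canonicalUnit("mechanical", "momentum"), "N·s")
  expect_error(canonicalUnit("chemical", "momentum"), class = "E_NO_SUCH_PROPERTY")
  expect_error(canonicalUnit("thermal_unknown", "force"), class = "E_NO_SUCH_PROPERTY")
})

test_that("constitutive units reduce dimensionally to their defining quotients", {
  # mechanical inductance N·s/(m/s) is a mass
  expect_equal(unitDimensions("mechanical", "constitutive.inductance"),
               c(m = 0L, kg = 1L, s = 0L, A = 0L, mol = 0L))
  # every registered constitutive class: dims equal the mandated quotient
  rules <- list(
    "constitutive.resistance"    = c("force", "flow"),
    "constitutive.conductance"   = c("flow", "force"),
    "constitutive.capacitance"   = c("amount", "force"),
    "constitutive.inductance"    = c("momentum", "flow"),
    "constitutive.rate_constant" = c("flow", "amount"))
  cls <- propertyClasses()
  for (d in biophysicalDomains()$id) {
    for (cat in names(rules)) {
      if (!any(cls$domain == d & cls$category == cat)) next
      nd <- rules[[cat]]
      expect_equal(unitDimensions(d, cat),
                   unitDimensions(d, nd[1]) - unitDimensions(d, nd[2]),
                   info = paste(d, cat))
    }
    # flow is amount per unit time in every domain
    expect_equal(unitDimensions(d, "flow") - unitDimensions(d, "amount"),
                 c(m = 0L, kg = 0L, s = -1L, A = 0L, mol = 0L), info = d)
  }
})

test_that("exactly one class per (domain, category) pair; chemical momentum absent", {
  cls <- propertyClasses()
  for (d in c("electrical", "fluid", "chemical", "mechanical"))
    for (cat in c("amount", "force", "flow"))
      expect_equal(sum(cls$domain == d & cls$category == cat), 1L, info = paste(d, cat))
  expect_equal(sum(cls$domain == "chemical" & cls$category == "momentum"), 0L)
  expect_equal(sum(cls$domain == "chemical" & cls$category == "constitutive.inductance"), 0L)
  expect_false(any(duplicated(cls$id)))
})

test_that("analogy map is a category-preserving bijection with involution", {
  expect_equal(analogOf("electrical.force", "fluid")$label, "Fluid pressure")
  expect_equal(analogOf("fluid.amount", "chemical")$label, "Molar amount")
  expect_error(analogOf("mechanical.momentum", "chemical"), class = "E_NO_SUCH_PROPERTY")
  expect_error(analogOf("electrical.constitutive.resistance", "fluid"),
               class = "E_NO_SUCH_PROPERTY")
  doms <- c("electrical", "fluid", "chemical", "mechanical")
  cls <- propertyClasses()
  dynamical <- cls[cls$category %in% c("amount", "momentum", "force", "flow"), ]
  for (i in seq_len(nrow(dynamical))) {
    p <- dynamical[i, ]
    for (d2 in setdiff(doms, p$domain)) {
      q <- tryCatch(analogOf(p$id, d2), physdepError = function(e) NULL)
      if (is.null(q)) {
        expect_equal(p$category, "momentum")  # only absent entry
        next
      }
      expect_equal(q$category, p$category)
      expect_equal(analogOf(q$id, p$domain)$id, p$id)  # round trip
    }
  }
})

test_that("dependency catalogue lists every kind with its role signature", {
  cat_ <- dependencyCatalog()
  expect_gte(length(cat_), 12L)
  res <- cat_$resistive$roles
  expect_equal(res$flow_player$max, 1L)
  expect_setequal(names(res),
                  c("flow_player", "force_player_high", "force_player_low", "constitutive"))
  expect_true("constitutive.resistance" %in% res$constitutive$categories)
  cap <- cat_$capacitive$roles
  expect_equal(cap$force_player_high$min, 1L)
  expect_equal(cap$amount_player$min, 1L)
  expect_equal(cap$constitutive$categories, "constitutive.capacitance")
  expect_true(all(c("boundary_flow", "boundary_force", "summation", "spatial",
                    "resistive", "mass_action", "diffusion", "transformer",
                    "transducer", "capacitive", "inductive", "transactor") %in% names(cat_)))
  expect_error(dependencyKind("frobnicate"), class = "E_SCHEMA")
})

test_that("a domain registered through the hook gets a full derived unit row", {
  snapshot <- as.list(physdep:::.registry)
  on.exit({
    rm(list = ls(physdep:::.registry), envir = physdep:::.registry)
    for (n in names(snapshot)) assign(n, snapshot[[n]], envir = physdep:::.registry)
  })
  registerDomain("thermal", "Thermal",
                 units = list(force = "K", flow = "W/K", amount = "J/K", momentum = NULL),
                 unitDims = list("K" = c(), "W/K" = c(m = 2, kg = 1, s = -3),
                                 "J/K" = c(m = 2, kg = 1, s = -2)))
  expect_equal(canonicalUnit("thermal", "force"), "K")
  expect_equal(canonicalUnit("thermal", "constitutive.resistance"), "K/(W/K)")
  expect_error(canonicalUnit("thermal", "momentum"), class = "E_NO_SUCH_PROPERTY")
  expect_equal(analogOf("thermal.force", "electrical")$id, "electrical.force")
  expect_error(registerDomain("thermal", "again", units = list(force = "K", flow = "W/K", amount = "J/K")),
               class = "E_DUPLICATE_ID")
})

test_that("taxonomy exports as parseable YAML covering all classes and kinds", {
  txt <- writeTaxonomyYAML()
  doc <- yaml::yaml.load(txt)
  expect_equal(doc$format, "physdep-taxonomy")
  expect_equal(length(doc$property_classes), nrow(propertyClasses()))
  expect_equal(length(doc$dependency_kinds), length(dependencyCatalog()))
})
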