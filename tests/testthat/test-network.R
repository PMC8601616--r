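# Small annotated model: A -> B -> C with ATP/ADP recycling on r2, an
# extracellular transport step and an unconnected D -> E branch.
net_model <- function() {
  mets <- data.frame(
    id = c("A_c", "B_c", "C_c", "atp_c", "adp_c", "D_c", "E_c"),
    name = c("A", "B", "C", "ATP", "ADP", "D", "E"),
    compartment = "c", stringsAsFactors = FALSE)
  #       r1      r2      r3      r4      r5
  S <- matrix(c(
    -1,  0,  0,  0,  0,   # A
     1, -1,  0,  0,  0,   # B
     0,  1, -1,  0,  0,   # C
     0, -1,  0,  0,  1,   # ATP  (r2 uses ATP, r5 makes it)
     0,  1,  0,  0, -1,   # ADP
     0,  0,  0, -1,  0,   # D
     0,  0,  0,  1,  0),  # E
    nrow = 7, byrow = TRUE)
  rx <- data.frame(
    id = paste0("r", 1:5), name = paste0("r", 1:5),
    subsystem = c("Glycolysis", "Glycolysis", "Extracellular transport",
                  "Other", "Energy"),
    reversible = FALSE, stringsAsFactors = FALSE)
  metabolic_model("net", mets, rx, S, rep(0, 5), rep(10, 5))
}

mod <- function(ids, component = 1L, label = "c1")
  structure(list(component = component, condition_label = label,
                 members = data.frame(reaction_id = ids,
                                      loading = rep(1, length(ids)),
                                      stringsAsFactors = FALSE)),
            class = "module")

test_that("reactions sharing only ubiquitous metabolites are not connected", {
  m <- net_model()
  g <- build_reaction_graph(list(mod(c("r2", "r5"))), m)
  # r2 and r5 share only ATP/ADP, which are on the ubiquitous list
  expect_equal(igraph::ecount(g), 0L)
  expect_equal(igraph::vcount(g), 2L)
  # with an empty ubiquitous list the ATP/ADP link appears
  g2 <- build_reaction_graph(list(mod(c("r2", "r5"))), m, ubiq = character())
  expect_equal(igraph::ecount(g2), 1L)
  e <- igraph::edge_attr(g2, "metabolites")
  expect_setequal(strsplit(e, ",")[[1]], c("atp_c", "adp_c"))
})

test_that("nodes are the union of module members with counts and flags", {
  m <- net_model()
  mods <- list(mod(c("r1", "r2")), mod(c("r2", "r3"), component = 2L))
  g <- build_reaction_graph(mods, m, significant_ids = "r1")
  expect_equal(igraph::vcount(g), 3L)
  expect_setequal(igraph::V(g)$name, c("r1", "r2", "r3"))
  v <- igraph::vertex_attr(g)
  expect_equal(v$module_count[v$name == "r2"], 2L)   # in both modules
  expect_equal(v$modules[v$name == "r2"], "c1:1,c1:2")
  expect_true(v$significant[v$name == "r1"])
  expect_false(v$significant[v$name == "r2"])
  # extracellular transport is flagged hidden, still present
  expect_true(v$hidden[v$name == "r3"])
  # r1-r2 share B, r2-r3 share C; r1-r3 share nothing
  expect_equal(igraph::ecount(g), 2L)
  expect_error(build_reaction_graph(list(mod("zzz")), m), "not in model")
})

test_that("first-neighbour expansion pulls in adjacent model reactions", {
  m <- net_model()
  g <- build_reaction_graph(list(mod("r1")), m)
  expect_equal(igraph::vcount(g), 1L)
  gx <- expand_first_neighbors(g, m)
  # r2 shares B with r1; r4/r5 touch no metabolite of r1 (ATP is ubiquitous)
  expect_setequal(igraph::V(gx)$name, c("r1", "r2"))
  expect_true(igraph::V(gx)$first_neighbour[igraph::V(gx)$name == "r2"])
  expect_false(igraph::V(gx)$first_neighbour[igraph::V(gx)$name == "r1"])
  expect_equal(igraph::ecount(gx), 1L)
})

test_that("graph exports round-trip through the tables", {
  m <- net_model()
  mods <- list(mod(c("r1", "r2")), mod(c("r2", "r3"), component = 2L))
  g <- build_reaction_graph(mods, m, significant_ids = "r2")
  pre <- tempfile("graph_")
  paths <- export_graph(g, pre)
  expect_true(all(file.exists(paste0(pre, c("_nodes.txt", "_edges.txt", ".graphml")))))
  b <- read_graph_tables(pre)
  expect_equal(igraph::vcount(b), igraph::vcount(g))
  expect_equal(igraph::ecount(b), igraph::ecount(g))
  expect_setequal(igraph::V(b)$name, igraph::V(b)$name)
  vb <- igraph::vertex_attr(b); vg <- igraph::vertex_attr(g)
  ob <- order(vb$name); og <- order(vg$name)
  expect_identical(vb$modules[ob], vg$modules[og])
  expect_identical(vb$significant[ob], vg$significant[og])
  expect_identical(vb$module_count[ob], vg$module_count[og])
  gm <- igraph::read_graph(paste0(pre, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(gm), igraph::vcount(g))
  # byte-stable: exporting again writes identical files
  pre2 <- tempfile("graph_")
  export_graph(g, pre2)
  expect_identical(readLines(paste0(pre, "_nodes.txt")),
                   readLines(paste0(pre2, "_nodes.txt")))
  expect_identical(readLines(paste0(pre, "_edges.txt")),
                   readLines(paste0(pre2, "_edges.txt")))
})

test_that("metabolic map is bipartite with substrate/product direction", {
  m <- net_model()
  g <- build_reaction_graph(list(mod(c("r1", "r2", "r3"))), m)
  mp <- build_metabolic_map(g, "Glycolysis", m)
  v <- igraph::vertex_attr(mp)
  expect_setequal(v$name[v$type == "reaction"], c("r1", "r2"))
  # ATP/ADP excluded as ubiquitous; A, B, C remain
  expect_setequal(v$name[v$type == "metabolite"], c("A_c", "B_c", "C_c"))
  # direction: A -> r1 -> B -> r2 -> C
  el <- igraph::as_edgelist(mp)
  expect_true(any(el[, 1] == "A_c" & el[, 2] == "r1"))
  expect_true(any(el[, 1] == "r1" & el[, 2] == "B_c"))
  expect_true(any(el[, 1] == "r2" & el[, 2] == "C_c"))
  expect_error(build_metabolic_map(g, "Nope", m), "no reactions")
})

test_that("single module view induces exactly that module's nodes", {
  m <- net_model()
  mods <- list(mod(c("r1", "r2")), mod(c("r2", "r3"), component = 2L))
  g <- build_reaction_graph(mods, m)
  s <- single_module_view(g, "c1:2")
  expect_setequal(igraph::V(s)$name, c("r2", "r3"))
  expect_error(single_module_view(g, "c1:9"), "unknown module")
})

test_that("the ubiquitous list contains the expected currency metabolites", {
  u <- ubiquitous_metabolites()
  expect_true(all(c("ATP", "ADP", "NADH", "H2O", "CO2", "CoA") %in% u))
  expect_equal(length(u), 53L)
})
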