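test_that("minimal KGML yields two single nodes and one activation edge", {
  g <- parse_kgml(kgml_two_gene())
  expect_s3_class(g, "pathway_graph")
  expect_length(g$nodes, 2)
  expect_setequal(vapply(g$nodes, `[[`, "", "kind"),
                  c("single", "single"))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$sign, "activation")
})

test_that("relation subtype semantics follow the activation/inhibition table", {
  expect_equal(classify_relation("expression"), "activation")
  expect_equal(classify_relation("phosphorylation"), "activation")
  expect_equal(classify_relation("dephosphorylation"), "activation")
  expect_equal(classify_relation("indirect effect"), "activation")
  expect_equal(classify_relation("compound"), "activation")
  expect_equal(classify_relation("ubiquitination"), "inhibition")
  expect_equal(classify_relation("inhibition"), "inhibition")
  expect_equal(classify_relation("repression"), "inhibition")
  # inhibitory label dominates: a phosphorylation that inhibits
  expect_equal(classify_relation(c("phosphorylation", "inhibition")),
               "inhibition")
  # order-invariance
  labs <- c("inhibition", "expression", "phosphorylation")
  for (i in 1:5) {
    perm <- sample(labs)
    expect_equal(classify_relation(perm), "inhibition")
  }
  expect_warning(s <- classify_relation("frobnication"), "unknown")
  expect_equal(s, "activation")
  expect_error(classify_relation(character(0)), "empty")
})

test_that("a doubly-subtyped phosphorylation+inhibition relation is an inhibition edge", {
  g <- parse_kgml(kgml_two_gene(
    '<subtype name="phosphorylation" value="+p"/>
     <subtype name="inhibition" value="--|"/>'))
  expect_equal(g$edges$sign, "inhibition")
})

test_that("group entries collapse to a single complex node", {
  doc <- kgml_doc(
    '<entry id="1" name="toy:g1" type="gene"/>
     <entry id="2" name="toy:g2" type="gene"/>
     <entry id="3" name="toy:g3" type="gene"/>
     <entry id="4" name="undefined" type="group">
       <component id="1"/><component id="2"/>
     </entry>',
    '<relation entry1="4" entry2="3" type="PPrel">
       <subtype name="activation" value="--&gt;"/></relation>')
  g <- parse_kgml(doc)
  expect_length(g$nodes, 2)
  kinds <- vapply(g$nodes, `[[`, "", "kind")
  cplx <- g$nodes[[names(kinds)[kinds == "complex"]]]
  expect_setequal(cplx$genes, c("toy:g1", "toy:g2"))
  expect_equal(nrow(g$edges), 1)
})

test_that("binding/association relations merge endpoints into a complex", {
  doc <- kgml_doc(
    '<entry id="1" name="toy:g1" type="gene"/>
     <entry id="2" name="toy:g2" type="gene"/>
     <entry id="3" name="toy:g3" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel">
       <subtype name="binding/association" value="---"/></relation>
     <relation entry1="2" entry2="3" type="PPrel">
       <subtype name="activation" value="--&gt;"/></relation>')
  g <- parse_kgml(doc)
  kinds <- vapply(g$nodes, `[[`, "", "kind")
  expect_equal(sort(unname(kinds)), c("complex", "single"))
  expect_equal(nrow(g$edges), 1)
})

test_that("multi-gene entries become alternatives nodes; each KGML gene lands in exactly one node", {
  doc <- kgml_doc(
    '<entry id="1" name="toy:g1 toy:g2 toy:g3" type="gene"/>
     <entry id="2" name="toy:g4" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel">
       <subtype name="activation" value="--&gt;"/></relation>')
  g <- parse_kgml(doc)
  kinds <- vapply(g$nodes, `[[`, "", "kind")
  expect_true("alternatives" %in% kinds)
  all_genes <- unlist(lapply(g$nodes, `[[`, "genes"))
  expect_equal(anyDuplicated(all_genes), 0L)
  expect_setequal(all_genes, paste0("toy:g", 1:4))
})

test_that("compound entries are spliced into a direct activation edge", {
  doc <- kgml_doc(
    '<entry id="1" name="toy:g1" type="gene"/>
     <entry id="2" name="cpd:C00076" type="compound"/>
     <entry id="3" name="toy:g2" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PCrel">
       <subtype name="compound" value="2"/></relation>
     <relation entry1="2" entry2="3" type="PCrel">
       <subtype name="compound" value="2"/></relation>')
  g <- parse_kgml(doc)
  expect_length(g$nodes, 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$sign, "activation")
})

test_that("map-link entries are dropped with a warning and malformed input errors", {
  doc <- kgml_doc(
    '<entry id="1" name="toy:g1" type="gene"/>
     <entry id="2" name="path:toy99" type="map"/>
     <entry id="3" name="toy:g2" type="gene"/>',
    '<relation entry1="1" entry2="3" type="PPrel">
       <subtype name="activation" value="--&gt;"/></relation>
     <relation entry1="1" entry2="2" type="maplink">
       <subtype name="compound" value="9"/></relation>')
  expect_warning(g <- parse_kgml(doc), "map")
  expect_length(g$nodes, 2)
  expect_error(parse_kgml("<pathway><entry"), "malformed")
  expect_error(suppressWarnings(parse_kgml(kgml_doc(
    '<entry id="1" name="toy:g1" type="gene"/>',
    '<relation entry1="1" entry2="99" type="PPrel">
       <subtype name="activation" value="-"/></relation>'))),
    "unknown entry")
})

test_that("JSON dialect round-trips a graph identically", {
  g <- toy_pathways(1)$fig6
  json <- write_pathway_json(g)
  g2 <- read_pathway_json(json)
  expect_equal(g2, g)
  # and KGML-parsed graphs survive the round trip too
  gk <- parse_kgml(kgml_two_gene())
  expect_equal(read_pathway_json(write_pathway_json(gk)), gk)
})

test_that("JSON schema violations are reported with the offending field path", {
  expect_error(read_pathway_json('{"pathway_id": "x", "nodes": []}'),
               "nodes")
  expect_error(read_pathway_json(
    '{"pathway_id": "x", "nodes": [{"id": "A", "kind": "single"}]}'),
    "\\$nodes\\[1\\]\\$genes")
  expect_error(read_pathway_json(
    paste0('{"pathway_id": "x",',
           ' "nodes": [{"id": "A", "kind": "single", "genes": ["g"]},',
           '           {"id": "B", "kind": "single", "genes": ["h"]}],',
           ' "edges": [{"from": "A", "to": "B"}]}')),
    "\\$edges\\[1\\]\\$sign")
})

test_that("GraphML export carries signs and round-trips counts through igraph", {
  g <- toy_pathways(1)$fig6
  xml <- write_graphml(g)
  expect_match(xml, "activation")
  tf <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, tf)
  gi <- igraph::read_graph(tf, format = "graphml")
  expect_equal(igraph::vcount(gi), length(g$nodes))
  expect_equal(igraph::ecount(gi), nrow(g$edges))
  # edge count equals the JSON fixture's edge count
  gj <- read_pathway_json(write_pathway_json(g))
  expect_equal(igraph::ecount(gi), nrow(gj$edges))
})

test_that("pathway_graph enforces its structural invariants", {
  n2 <- list(A = node_spec("single", "g1"), B = node_spec("single", "g2"))
  expect_error(pathway_graph("p", list(), data.frame()), "empty")
  expect_error(pathway_graph("p", n2,
                             data.frame(from = "A", to = "Z",
                                        sign = "activation")),
               "unknown nodes")
  expect_error(pathway_graph("p", n2,
                             data.frame(from = "A", to = "A",
                                        sign = "activation")),
               "self-edges")
  expect_error(node_spec("single", c("g1", "g2")), "exactly one")
  expect_error(node_spec("complex", "g1"), "at least two")
})
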