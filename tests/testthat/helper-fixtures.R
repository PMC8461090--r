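# Shared fixtures built in code.

# small count matrix, samples x taxa
toy_table <- function() {
  m <- matrix(c(6, 2, 0,
                2, 2, 4,
                1, 0, 9), 3, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c")))
  m
}

# balanced 4-tip tree used in the UniFrac worked example
four_tip_tree <- function() {
  ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
}

# 12-tip tree with two dense clusters separated by a long stem
two_clade_tree <- function() {
  mk <- function(labs) paste0(
    "(((", labs[1], ":0.01,", labs[2], ":0.01):0.01,(", labs[3],
    ":0.01,", labs[4], ":0.01):0.01):0.01,(", labs[5], ":0.01,",
    labs[6], ":0.01):0.02):1")
  ape::read.tree(text = paste0(
    "(", mk(paste0("a", 1:6)), ",", mk(paste0("b", 1:6)), ");"))
}

# brute-force unweighted UniFrac by branch enumeration
unifrac_brute <- function(tree, pres_a, pres_b) {
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    desc[[po$edge[e, 1]]] <- c(desc[[po$edge[e, 1]]], desc[[po$edge[e, 2]]])
  uniq <- shared <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- desc[[tree$edge[e, 2]]]
    inA <- any(tips %in% pres_a); inB <- any(tips %in% pres_b)
    if (inA && inB) shared <- shared + tree$edge.length[e]
    else if (inA || inB) uniq <- uniq + tree$edge.length[e]
  }
  uniq / (uniq + shared)
}

# brute-force Bray-Curtis for two count vectors
bray_brute <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
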