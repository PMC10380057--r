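# ctna — conformational transition networks and solvation analysis

`ctna` is an R toolkit for analysing molecular-dynamics trajectories of
flexible peptides and their solvent environment. It targets the
disorder-to-order question for intrinsically disordered peptides such as
the amyloid-beta monomer: which conformational basins does the chain
visit, how does it move between them, and does the surrounding water or
ion atmosphere change when a co-solute is present?

The core object is the **transition network** (TN). Every frame is
projected onto a descriptor triple

> S(t) = [ Nalpha(t), Nbeta(t), dNC(t) ]

— the number of helical residues, the number of sheet residues (both from
a geometry-only backbone-dihedral classifier), and the end-to-end
C-alpha distance in Angstrom (binned at 1 Angstrom). Identical binned
triples form one discrete state; directed transition counts between
states over each trajectory segment form a weighted graph. Modularity
communities of that graph are the free-energy basins; node populations
are self-transition counts, displayed on a linear 1–10 size scale;
networks export to GEXF/GraphML for Gephi.

Around the TN sit the companion analyses used to interrogate the solvent:

* oxygen–oxygen RDFs and the **translational order parameter**
  T = (1/zeta_c) * integral of |g(zeta) − 1| d zeta up to zeta_c = 2.8,
  with zeta = r * rho^(1/3) (T = 0 for an ideal gas);
* the **tetrahedral order parameter**
  q = 1 − (3/8) * sum over neighbor pairs of (cos psi + 1/3)^2
  over each oxygen's four nearest neighbors (1 = perfect tetrahedron,
  mean 0 for random directions);
* **hydrogen-bond lifetime kinetics**: binary existence traces, pooled
  multi-origin intermittent autocorrelation c(t), stretched-exponential
  fits c(t) = exp(−(t/tau)^beta) and the gamma-function mean lifetime
  <tau> = (tau/beta) * Gamma(1/beta);
* residue **contact-probability maps** (10 Angstrom heavy-atom rule),
  **ion radial distributions** around charged groups, and formal **net
  charges** of peptides and glycosaminoglycan chains;
* a **synthetic-data module** that generates Markov-switching peptide
  trajectories with geometry-built backbones, water configurations from
  ideal gas to diamond lattice, renewal-process H-bond traces and toy ion
  systems — every pipeline stage can be tested against known ground
  truth.

See `vignettes/transition-networks.Rmd` for the models, conventions and
numerical choices.

## Worked example

```r
library(ctna)

spec <- abeta_like_spec(n_frames = 2000, seed = 42)  # coil/helix/hairpin
ens  <- realize_trajectory(spec)
ss   <- project_trajectory(ens)
net  <- build_transition_matrix(ss)
net  <- detect_communities(net, seed = 1)
net$summary <- summarize_communities(net, ss)
net
print(net$summary, digits = 3)
```

```
Transition network: 114 states, 1879 inter-state transitions, lag 1
  communities: 3
  community n_states n_frames fraction Nalpha Nbeta   dNC
1         1       40      240    0.120      0  10.1  78.6
2         2       27      969    0.484      0   0.0 119.8
3         3       47      791    0.396     12   0.0  74.9
```

The three communities recover the three designed macrostates: a compact
sheet-rich basin (Nbeta ≈ 10, dNC ≈ 79 — the beta-hairpin), an extended
disordered basin (no secondary structure, dNC ≈ 120), and a helical basin
(Nalpha = 12, the designed 10–21 helix). The fractions are the empirical
macrostate occupancies of this particular 2000-frame realization.
`export_network(net, "tn.gexf")` writes the graph with all descriptor,
population, size and community attributes for Gephi.

```r
net_charge("DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA")  # Abeta1-42
#> [1] -3
net_charge(c(GalNAc4S = 8, GlcUA = 8))                    # C4S 16-mer
#> [1] -16
```

A command-line front end (`inst/scripts/ctna-cli.R`) exposes the same
pipeline as subcommands `tn`, `solvent`, `hbonds`, `contacts`, `ions`,
`charge` and `synth`.

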