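# hydrolyzer

Template-driven enumeration of hydrolysis reactions and prediction of
their Gibbs free energies (ΔG_r, kcal/mol) with a reaction-graph neural
network, in pure R.

Hydrolysis — cleavage of a substrate bond with water acting as both
reactant and solvent — underlies polymer recycling, drug stability and
environmental degradation, and its thermodynamics shift strongly with
pH.  `hydrolyzer` is aimed at computational chemists who want to screen
candidate molecules for hydrolytic stability without running quantum
chemistry on every pathway.  It provides:

* **A functional-group template engine.**  Thirteen hydrolyzable groups
  (esters, lactones, amides, lactams, imides, nitriles, carbamates,
  ureas, cyclic carbonates, epoxides, aliphatic fluorides, enamines and
  N–S compounds) are detected by substructure matching on
  explicit-hydrogen molecular graphs; bond-edit templates then delete
  the scissile bond `a` and one water O–H bond `b`, and form the bonds
  `c` (substrate–OH) and `d` (leaving group–H) to yield the products.
  Nitriles cascade through the intermediate amide (two reactions per
  nitrile); carbamates and ureas decompose to three products including
  CO₂.
* **pH-dependent reaction schemes.**  Besides the neutral scheme, the
  acid-catalyzed scheme protonates the most electron-rich site (+1
  substrate, two waters, hydronium co-product) and the base-catalyzed
  scheme hydroxylates the electrophilic site (−1 substrate, hydroxide
  co-product).  Every emitted reaction conserves its element multiset,
  its total charge, and carries a total atom map over all atoms,
  hydrogens included.
* **Union reaction graphs.**  For learning, a reaction is encoded as a
  single heterograph whose atom nodes are the mapped atoms, whose bond
  nodes are the *union* of reactant-side and product-side bonds (so any
  number of simultaneous bond breakings and formations is represented),
  and whose one global node carries molecule-level features plus a
  functional-group one-hot.  Node features are product-minus-reactant
  differences; a bond absent on one side contributes a zero vector.
* **A gated graph-convolution network.**  Message passing alternates
  bond ← atoms+global, atom ← bonds+global and global ← aggregates
  updates through sigmoid-gated residual blocks, followed by a
  permutation-invariant pooling (mean, weighted mean, self-attention or
  set2set) and a dense regression head.  Forward and backward passes
  are implemented in base R matrix algebra (gradients verified against
  numerical differentiation) and are vectorized over batches of graphs.
* **A synthetic reaction generator** that drives the real template
  engine over randomized scaffolds and labels each reaction with an
  additive bond-increment surrogate energy — so the full train/evaluate
  loop is exercisable offline, with no quantum-chemistry data.

## Worked example

```r
library(hydrolyzer)

mol  <- parse_molecule("N#CCC(=O)OCC")          # ethyl cyanoacetate
rxns <- enumerate_hydrolysis(mol, "neutral")
for (r in rxns) print(r)
```

```
<neutral hydrolysis of nitrile | C(CC(=O)OCC)#N.O>>C(CC(=O)OCC)(N)=O>
<neutral hydrolysis of amide | C(CC(=O)OCC)(N)=O.O>>C(CC(=O)OCC)(=O)O.N>
<neutral hydrolysis of carboxylic acid ester | C(CC(=O)OCC)#N.O>>C(CC(=O)O)#N.CCO>
```

Three pathways: the nitrile hydrates to the amide, the amide (cascade)
cleaves to the malonate half-acid plus ammonia, and the ester cleaves
to the acid plus ethanol.  Training on synthetic fixtures and
predicting:

```r
fx  <- generate_fixtures(fixture_spec(n = 2000, seed = 21, noise_sd = 0.5))
cfg <- model_config(embedding = 48, conv_layers = 3, pooling = "mean",
                    lr = 3e-3, epochs = 120, seed = 5)
mdl <- train(lapply(fx, `[[`, "reaction"), cfg)
evaluate(mdl, lapply(fx[1:200], function(r) build_reaction_graph(r$reaction)))
```

```
n=200  MAE 1.713  RMSE 2.197  R2 0.991  sign acc 97.0%
error bins (kcal/mol): <2: 128  2-5: 67  5-10: 5  >10: 0
```

(Numbers printed by this exact run; the labels here are the synthetic
surrogate, not quantum-chemistry energies.)  The same loop is available
from a shell via `inst/cli/hydrolyzer` with the subcommands
`enumerate`, `fixtures`, `preprocess`, `train`, `evaluate` and
`predict`; `predict` lists every hydrolysis pathway of a molecule with
its predicted ΔG_r, most exergonic first.

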