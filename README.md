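# kinmech

Automated discovery of the simplest mass-action reaction mechanism
consistent with concentration–time data.

Chemists and reaction engineers routinely face the inverse problem: the
overall stoichiometry of a transformation is known (say 4A → B + C), a
handful of kinetic experiments have been run, but the network of elementary
steps — including intermediates that were never measured — is not known.
`kinmech` answers it with a parsimony-first pipeline:

1. **Enumerate** every physically sensible mechanism of a given complexity.
   A mechanism is an integer matrix (rows = elementary steps, columns =
   species; negative = consumed, positive = produced) and a pruned
   backtracking search walks the space that brute force cannot (a 4×5
   matrix over entries −2…2 already has 5²⁰ ≈ 9.5 × 10¹³ assignments).
2. **Translate** each matrix into a mass-action ODE model: step *j* has
   rate *r*ⱼ = *k*ⱼ ∏ᵢ *C*ᵢ^|νⱼᵢ| over its reactants, and
   d*C*ᵢ/dt = Σⱼ νⱼᵢ *r*ⱼ.
3. **Fit** the rate constants to all experiments at once by multistart
   L-BFGS-B minimisation of the sum of squared errors, bounds [0, 10].
4. **Select** by the Akaike information criterion, AIC = 2·NLL + 2·*d*
   (concentrated Gaussian NLL = (*N*/2)·log(SSE/*N*)); the mechanism class
   grows by one step and one hidden intermediate per iteration until the
   AIC stops improving, and the previous winner is returned.

A Hunter–Reiner experiment designer (`design_experiment()`) proposes the
initial conditions that best discriminate between two rival fitted models,
closing the loop between modelling and experimentation.

## Worked example

Discover the aldol-condensation mechanism from five simulated experiments
in which only the reactants A (acetophenone), B (benzaldehyde) and the
products C (chalcone), D (water) are observed:

```r
library(kinmech)

data <- generate_aldol(seed = 42)        # 5 experiments, 30 samples, noise sd 0.15
st   <- parse_stoichiometry("A:-1,B:-1,C:1,D:1")
disc <- run_discovery(st, data, min_steps = 1, min_species = 4,
                      fit = fit_config(seed = 7), max_iterations = 3)
print(disc)
```

```
Mechanism discovery: 3 iteration(s), terminated by max_iterations
  iter 1 (1 x 4): 1 candidate(s), best AIC 116.565
  iter 2 (2 x 5): 10 candidate(s), best AIC -703.484
  iter 3 (3 x 6): 176 candidate(s), best AIC -2287.44
Winner (iteration 3):
Mass-action model: 3 step(s), 6 species
  k1: A -> E
  k2: B + E -> F
  k3: F -> C + D
k_hat: 0.7622, 0.2881, 0.6856
```

Each rung enumerates every feasible matrix at that size (1, then 10, then
176 candidates), fits them all, and keeps the AIC minimum.  The winner is
the textbook three-step pathway — enolization of the ketone (A → E),
carbon–carbon coupling with the aldehyde (E + B → F), dehydration to the
enone (F → C + D) — with rate constants within a few percent of the values
(0.759, 0.293, 0.681) that generated the data, even though the enolate E
and the β-hydroxy adduct F were never observed.  AIC values are comparable
within a dataset only; lower is better.

The same functions drive the other bundled systems
(`generate_hypothetical()`, `generate_fructose()`), and a thin command-line
front end wraps them:

```sh
exec/kinmech enumerate --stoich "A:-4,B:1,C:1" --steps 3 --intermediates 1 --out mechs.json
exec/kinmech simulate-case --name fructose --seed 42 --out data/
exec/kinmech discover --data data/fructose.csv --stoich "A:-1,B:3,C:1" \
    --min-steps 3 --min-species 5 --seed 7 --out result.json
```

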