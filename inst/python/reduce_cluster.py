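"""2-D embedding (UMAP) and density clustering (HDBSCAN) worker.

Invoked by the R package as a subprocess:

    python reduce_cluster.py MODE --infile pcs.tsv --outfile out.tsv \
        --seed 42 --n-neighbors 15 --min-dist 0.1 --min-cluster-size 5

MODE is one of:
  umap     -- embed the input matrix to 2-D; writes x<TAB>y per row
  hdbscan  -- cluster the (2-column) input; writes one integer label per row
  both     -- embed then cluster; writes x<TAB>y<TAB>label per row

With a fixed --seed the output is deterministic (UMAP is forced to a
single-threaded, seeded run by random_state).
"""

import argparse
import sys
import warnings

import numpy as np


def main() -> int:
    ap = argparse.ArgumentParser()
    ap.add_argument("mode", choices=["umap", "hdbscan", "both"])
    ap.add_argument("--infile", required=True)
    ap.add_argument("--outfile", required=True)
    ap.add_argument("--seed", type=int, default=42)
    ap.add_argument("--n-neighbors", type=int, default=15)
    ap.add_argument("--min-dist", type=float, default=0.1)
    ap.add_argument("--min-cluster-size", type=int, default=5)
    ap.add_argument("--min-samples", type=int, default=5)
    ap.add_argument("--cluster-selection-epsilon", type=float, default=0.5)
    ap.add_argument("--no-single-cluster", action="store_true")
    args = ap.parse_args()

    warnings.filterwarnings("ignore")
    X = np.loadtxt(args.infile, delimiter="\t", ndmin=2)

    if args.mode in ("umap", "both"):
        import umap  # imported lazily: pulls in numba JIT compilation

        n_neighbors = min(args.n_neighbors, X.shape[0] - 1)
        emb = umap.UMAP(
            n_components=2,
            n_neighbors=n_neighbors,
            min_dist=args.min_dist,
            metric="euclidean",
            random_state=args.seed,
        ).fit_transform(X)
    else:
        emb = X

    if args.mode == "umap":
        np.savetxt(args.outfile, emb, delimiter="\t", fmt="%.17g")
        return 0

    from sklearn.cluster import HDBSCAN

    labels = (
        HDBSCAN(
            min_cluster_size=args.min_cluster_size,
            min_samples=args.min_samples,
            cluster_selection_epsilon=args.cluster_selection_epsilon,
            allow_single_cluster=not args.no_single_cluster,
            metric="euclidean",
            copy=True,
        )
        .fit(emb)
        .labels_.astype(int)
    )

    if args.mode == "hdbscan":
        np.savetxt(args.outfile, labels[:, None], delimiter="\t", fmt="%d")
    else:
        out = np.column_stack([emb, labels])
        np.savetxt(args.outfile, out, delimiter="\t", fmt="%.17g\t%.17g\t%d")
    return 0


if __name__ == "__main__":
    sys.exit(main())
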