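"""Solve a batch of linearized 0-1 pixel-labeling programs with HiGHS.

Reads a JSON array of problems on stdin, writes a JSON array of solutions
on stdout. Each problem has binary pixel variables x (coefficients obj_x,
with ambiguous-fixed penalties folded in) and continuous edge variables e
in [0, 1] (coefficients obj_e <= 0), subject to e >= x_u - x_v and
e >= x_v - x_u; the objective is maximized.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def solve_one(p):
    n = int(p["n"])
    obj_x = np.atleast_1d(np.asarray(p.get("obj_x", []), dtype=float))
    obj_e = np.atleast_1d(np.asarray(p.get("obj_e", []), dtype=float))
    eu = np.atleast_1d(np.asarray(p.get("edge_u", []), dtype=int))
    ev = np.atleast_1d(np.asarray(p.get("edge_v", []), dtype=int))
    fv = np.atleast_1d(np.asarray(p.get("fold_var", []), dtype=int))
    pen1 = np.atleast_1d(np.asarray(p.get("fold_pen1", []), dtype=float))
    pen0 = np.atleast_1d(np.asarray(p.get("fold_pen0", []), dtype=float))

    # fold ambiguous-fixed penalties into the x coefficients:
    # pen1 is paid when x = 1, pen0 when x = 0 (constant terms dropped)
    for k in range(fv.size):
        obj_x[fv[k] - 1] += pen0[k] - pen1[k]

    m = eu.size
    c = -np.concatenate([obj_x, obj_e])  # milp minimizes
    constraints = []
    if m:
        rows, cols, vals = [], [], []
        for k in range(m):
            u, v, e = eu[k] - 1, ev[k] - 1, n + k
            rows += [2 * k] * 3 + [2 * k + 1] * 3
            cols += [u, v, e, u, v, e]
            vals += [1.0, -1.0, -1.0, -1.0, 1.0, -1.0]
        A = sparse.csr_matrix((vals, (rows, cols)), shape=(2 * m, n + m))
        constraints.append(LinearConstraint(A, -np.inf, 0.0))

    integrality = np.concatenate([np.ones(n), np.zeros(m)])
    res = milp(c=c, constraints=constraints, integrality=integrality,
               bounds=Bounds(0.0, 1.0))
    if res.status != 0:
        return {"status": "failed", "message": str(res.message)}
    return {"status": "optimal",
            "x": [int(round(v)) for v in res.x[:n]]}


def main():
    problems = json.load(sys.stdin)
    json.dump([solve_one(p) for p in problems], sys.stdout)


if __name__ == "__main__":
    main()
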