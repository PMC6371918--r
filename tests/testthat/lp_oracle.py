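"""Independent transportation-LP oracle for earth mover's distance.

Reads a JSON list of problems ({sa, sb, ca, cb}) and writes a JSON list of
optimal transport costs, solved as an explicit linear program with
scipy.optimize.linprog (HiGHS). Used only by the test suite as a reference
solution; the package's own solver never calls this.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(problem):
    sa = np.atleast_1d(np.array(problem["sa"], dtype=float))
    sb = np.atleast_1d(np.array(problem["sb"], dtype=float))
    ca = np.atleast_2d(np.array(problem["ca"], dtype=float))
    cb = np.atleast_2d(np.array(problem["cb"], dtype=float))
    sa = sa / sa.sum()
    sb = sb / sb.sum()
    m, n = len(sa), len(sb)
    cost = np.linalg.norm(ca[:, None, :] - cb[None, :, :], axis=2).ravel()
    a_eq, b_eq = [], []
    for i in range(m):
        row = np.zeros(m * n)
        row[i * n:(i + 1) * n] = 1.0
        a_eq.append(row)
        b_eq.append(sa[i])
    for j in range(n - 1):  # last column constraint is redundant
        row = np.zeros(m * n)
        row[j::n] = 1.0
        a_eq.append(row)
        b_eq.append(sb[j])
    res = linprog(cost, A_eq=np.array(a_eq), b_eq=np.array(b_eq),
                  bounds=(0, None), method="highs")
    assert res.status == 0, res.message
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    results = [solve(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
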