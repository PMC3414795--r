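#!/usr/bin/env python3
"""Exact-rational oracle for the two-library conditional count test.

Evaluates p(y|x) = (N2/N1)^y * (x+y)!/(x! y!) * (1+N2/N1)^-(x+y+1) and the
two-sided p-value (2F if F <= 1/2 else 2(1-F), F = sum_{i<=y} p(i|x)) in
exact rational arithmetic (stdlib fractions), printing 25 significant
decimal digits. Used only as an independent test oracle.

Usage:
  ac_exact.py prob Y X N1 N2
  ac_exact.py pval X Y N1 N2
  ac_exact.py grid XMAX YMAX N1 N2        (TSV: x, y, pval)
  ac_exact.py normsum X YMAX N1 N2        (sum_{y=0..YMAX} p(y|x))
"""
import math
import sys
from decimal import Decimal, getcontext
from fractions import Fraction

getcontext().prec = 30


def prob(y, x, n1, n2):
    r = Fraction(n2, n1)
    return r ** y * math.comb(x + y, y) * (1 + r) ** (-(x + y + 1))


def pval(x, y, n1, n2):
    F = sum(prob(i, x, n1, n2) for i in range(y + 1))
    v = 2 * F if F <= Fraction(1, 2) else 2 * (1 - F)
    return v


def fmt(fr):
    return str(Decimal(fr.numerator) / Decimal(fr.denominator))


def main(argv):
    mode = argv[1]
    a = [int(v) for v in argv[2:]]
    if mode == "prob":
        y, x, n1, n2 = a
        print(fmt(prob(y, x, n1, n2)))
    elif mode == "pval":
        x, y, n1, n2 = a
        print(fmt(pval(x, y, n1, n2)))
    elif mode == "grid":
        xmax, ymax, n1, n2 = a
        r = Fraction(n2, n1)
        for x in range(xmax + 1):
            # cumulative F maintained incrementally along y
            F = Fraction(0)
            term = (1 + r) ** (-(x + 1))  # p(0|x)
            for y in range(ymax + 1):
                if y > 0:
                    term = term * (x + y) * r / (y * (1 + r))
                F += term
                v = 2 * F if F <= Fraction(1, 2) else 2 * (1 - F)
                print("%d\t%d\t%s" % (x, y, fmt(v)))
    elif mode == "normsum":
        x, ymax, n1, n2 = a
        r = Fraction(n2, n1)
        term = (1 + r) ** (-(x + 1))
        total = term
        for y in range(1, ymax + 1):
            term = term * (x + y) * r / (y * (1 + r))
            total += term
        print(fmt(total))
    else:
        raise SystemExit("unknown mode " + mode)


if __name__ == "__main__":
    main(sys.argv)
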